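# Synthetic E/EQ digest experiments with known ground truth.
#
# The generator emulates the comparative degradomics design: a substrate is
# incubated with active (E) or inactive (EQ) protease, then digested with a
# working protease and quantified label-free. Cleavage events planted at
# known positions with known efficiencies leave the same statistical
# footprint the caller assumes: semi-specific peptides flanking the planted
# bond enriched in E, fully specific peptides spanning the bond depleted in
# E, and a large symmetric population of unaffected peptides -- including
# spurious semi-specific peptides, which in real LC-MS/MS data (in-source
# fragmentation, nonspecific proteolysis) are roughly as numerous as fully
# specific peptides and dominate the semi population.

# human proteome-average residue frequencies used for random test proteins
HUMAN_AA_FREQ <- c(
  A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, Q = 4.8, E = 7.1, G = 6.6,
  H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.1, F = 3.7, P = 6.3, S = 8.3,
  T = 5.4, W = 1.2, Y = 2.7, V = 6.0)

#' Configuration for a synthetic E/EQ experiment
#'
#' Defaults describe a compact but statistically faithful experiment: a
#' 300-residue substrate carrying 10 planted cleavage sites cut at 80%
#' efficiency, trypsin as working protease with up to 2 missed cleavages
#' and a 6-75 residue detectability window, log-normal peptide base
#' abundances (log2 mean 18, log2 sd 1.5, the scale of LFQ intensities),
#' 10% multiplicative noise per group, a spurious-semi-peptide rate of 1.7
#' per theoretical peptide (matching the semi:fully peptide ratio observed
#' in real E/EQ digests, where spurious semi-specific peptides outnumber
#' fully specific ones), and a 90% detection probability.
#'
#' @param seed Integer RNG seed; the simulation is a pure function of the
#'   configuration.
#' @param protein Optional [protein_record()]; when `NULL` a random protein
#'   of `protein_length` residues with human-average composition is drawn.
#' @param protein_length Length of the generated substrate (default 300).
#' @param planted_sites Optional data.frame with `p1_pos` and `fraction`
#'   columns; when `NULL`, `n_planted` positions are chosen so that neither
#'   flanking semi peptide is outside the length window and no position
#'   coincides with a working-protease site.
#' @param n_planted Number of auto-chosen planted sites (default 10).
#' @param cleavage_fraction Efficiency of auto-chosen sites (default 0.8).
#' @param working_proteases Subset of `c("trypsin", "gluc")`.
#' @param max_missed,length_range Digest settings (defaults 2 and
#'   `c(6, 75)`).
#' @param base_log2_mean,base_log2_sd Log-normal base-abundance parameters
#'   on the log2 scale (defaults 18 and 1.5).
#' @param noise_cv Fractional multiplicative noise per group (default 0.1).
#' @param background_semi_rate Expected number of spurious semi-specific
#'   peptides emitted per theoretical peptide (Poisson), symmetric between
#'   groups (default 1.7).
#' @param detect_prob Probability a generated peptide species is observed
#'   (default 0.9).
#' @param eq_trace_fraction EQ intensity of planted-site semi peptides as a
#'   fraction of base abundance (default 0.01), giving the faint both-group
#'   quantification real inactive controls show.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 7L, protein = NULL,
                             protein_length = 300L, planted_sites = NULL,
                             n_planted = 10L, cleavage_fraction = 0.8,
                             working_proteases = "trypsin",
                             max_missed = 2L, length_range = c(6L, 75L),
                             base_log2_mean = 18, base_log2_sd = 1.5,
                             noise_cv = 0.1, background_semi_rate = 1.7,
                             detect_prob = 0.9, eq_trace_fraction = 0.01) {
  stopifnot(all(working_proteases %in% c("trypsin", "gluc")),
            length(working_proteases) >= 1L,
            noise_cv >= 0, background_semi_rate >= 0,
            detect_prob > 0, detect_prob <= 1,
            eq_trace_fraction > 0, eq_trace_fraction <= 1)
  if (!is.null(planted_sites)) {
    stopifnot(all(c("p1_pos", "fraction") %in% names(planted_sites)),
              all(planted_sites$fraction > 0),
              all(planted_sites$fraction <= 1))
  }
  structure(list(
    seed = as.integer(seed), protein = protein,
    protein_length = as.integer(protein_length),
    planted_sites = planted_sites, n_planted = as.integer(n_planted),
    cleavage_fraction = cleavage_fraction,
    working_proteases = working_proteases,
    max_missed = as.integer(max_missed),
    length_range = as.integer(length_range),
    base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
    noise_cv = noise_cv, background_semi_rate = background_semi_rate,
    detect_prob = detect_prob, eq_trace_fraction = eq_trace_fraction),
    class = "synthetic_config")
}

#' Generate a random protein record
#'
#' @param length Number of residues.
#' @param id Record identifier.
#' @param freq Named residue frequency vector (default human average).
#' @return A [protein_record()]. Uses the current RNG state.
#' @export
random_protein <- function(length, id = "SYN1", freq = HUMAN_AA_FREQ) {
  protein_record(id, paste(sample(names(freq), length, replace = TRUE,
                                  prob = freq), collapse = ""),
                 description = "synthetic random protein")
}

#' Simulate an E/EQ digest experiment
#'
#' Deterministic given the configuration (including its seed). See
#' [synthetic_config()] for the generative model. Planted cleavage products
#' are re-digested with the working protease and the peptides whose one
#' terminus is the planted bond are emitted as semi-specific evidence with
#' `E = fraction * base` and a trace EQ intensity; fully specific peptides
#' spanning planted bonds have their E intensity multiplied by
#' `prod(1 - fraction)` over the spanned sites.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_experiment`: `observations` (peptide
#'   table with `obs_id`), `truth` (list with `planted` sites and
#'   per-observation `provenance`), `protein` (the substrate record).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  protein <- config$protein
  if (is.null(protein)) protein <- random_protein(config$protein_length)
  L <- protein_length(protein)
  rules <- lapply(config$working_proteases, protease_rule)
  names(rules) <- config$working_proteases

  planted <- config$planted_sites
  if (is.null(planted)) {
    planted <- choose_planted_sites(protein, rules, config)
  } else {
    planted <- planted[, c("p1_pos", "fraction"), drop = FALSE]
    if (any(planted$p1_pos < 1L | planted$p1_pos >= L)) {
      stop("planted p1_pos outside protein")
    }
    all_theoretical <- unique(unlist(lapply(rules, function(r)
      theoretical_sites(protein, r))))
    clash <- intersect(planted$p1_pos, all_theoretical)
    if (length(clash)) {
      warning("planted site(s) ", paste(clash, collapse = ", "),
              " coincide with working-protease sites and are invisible as",
              " semi evidence")
    }
  }

  rows <- list(); prov <- list()
  for (wp in config$working_proteases) {
    rule <- rules[[wp]]
    fully <- digest_protein(protein, rule, config$max_missed,
                            config$length_range)
    if (nrow(fully)) {
      base <- 2 ^ stats::rnorm(nrow(fully), config$base_log2_mean,
                               config$base_log2_sd)
      depl <- vapply(seq_len(nrow(fully)), function(i) {
        spanned <- planted$p1_pos >= fully$start[i] &
          planted$p1_pos < fully$end[i]
        prod(1 - planted$fraction[spanned])
      }, 0)
      fully$abundance_E <- base * depl * noise_factor(nrow(fully), config)
      fully$abundance_EQ <- base * noise_factor(nrow(fully), config)
      fully$n_missed <- NULL
      rows[[length(rows) + 1L]] <- fully
      prov[[length(prov) + 1L]] <- data.frame(
        provenance = rep("fully", nrow(fully)),
        planted_p1 = rep(NA_integer_, nrow(fully)))

      bg <- background_semi(fully, protein, rule, config)
      if (nrow(bg)) {
        bbase <- 2 ^ stats::rnorm(nrow(bg), config$base_log2_mean,
                                  config$base_log2_sd)
        bg$abundance_E <- bbase * noise_factor(nrow(bg), config)
        bg$abundance_EQ <- bbase * noise_factor(nrow(bg), config)
        rows[[length(rows) + 1L]] <- bg
        prov[[length(prov) + 1L]] <- data.frame(
          provenance = rep("background", nrow(bg)),
          planted_p1 = rep(NA_integer_, nrow(bg)))
      }
    }
    sem <- planted_semi_peptides(planted, protein, rule, config)
    if (nrow(sem)) {
      sbase <- 2 ^ stats::rnorm(nrow(sem), config$base_log2_mean,
                                config$base_log2_sd)
      frac <- planted$fraction[match(sem$planted_p1, planted$p1_pos)]
      sem$abundance_E <- frac * sbase * noise_factor(nrow(sem), config)
      sem$abundance_EQ <- config$eq_trace_fraction * sbase *
        noise_factor(nrow(sem), config)
      p1 <- sem$planted_p1
      sem$planted_p1 <- NULL
      rows[[length(rows) + 1L]] <- sem
      prov[[length(prov) + 1L]] <- data.frame(
        provenance = rep("planted", nrow(sem)), planted_p1 = p1)
    }
  }
  obs <- do.call(rbind, rows)
  provenance <- do.call(rbind, prov)
  keep <- stats::runif(nrow(obs)) <= config$detect_prob
  obs <- obs[keep, , drop = FALSE]
  provenance <- provenance[keep, , drop = FALSE]
  obs$obs_id <- seq_len(nrow(obs))
  provenance$obs_id <- obs$obs_id
  rownames(obs) <- NULL; rownames(provenance) <- NULL
  structure(list(observations = obs,
                 truth = list(planted = planted, provenance = provenance),
                 protein = protein),
            class = "synthetic_experiment")
}

noise_factor <- function(n, config) {
  if (config$noise_cv == 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, config$noise_cv))
}

# positions whose two flanking semi peptides (terminal peptides of the two
# cleavage products, complete re-digestion) both fall in the length window
# and that are not themselves working-protease sites
choose_planted_sites <- function(protein, rules, config) {
  L <- protein_length(protein)
  all_theoretical <- sort(unique(unlist(lapply(rules, function(r)
    theoretical_sites(protein, r)))))
  cand <- setdiff(seq.int(2L, L - 2L), all_theoretical)
  ok <- vapply(cand, function(p) {
    for (wp in names(rules)) {
      sem <- semi_at_site(p, protein, rules[[wp]], config, missed = 0L)
      if (nrow(sem) < 2L) return(FALSE)
    }
    TRUE
  }, TRUE)
  cand <- cand[ok]
  if (length(cand) < config$n_planted) {
    stop("cannot place ", config$n_planted, " detectable sites on a ",
         L, "-mer")
  }
  pos <- sort(sample(cand, config$n_planted))
  data.frame(p1_pos = pos, fraction = rep(config$cleavage_fraction,
                                          length(pos)))
}

# semi peptides with one terminus at the planted bond: terminal peptides of
# the two cleavage products after complete working-protease re-digestion
# (the dominant semi species; missed-cleavage variants are second order)
semi_at_site <- function(p1, protein, rule, config, missed = 0L) {
  L <- protein_length(protein)
  sites <- theoretical_sites(protein, rule)
  seqs <- protein$sequence
  out <- list()
  # left product ends at p1: peptide (last site < p1) + 1 .. p1
  left_start <- max(c(0L, sites[sites < p1])) + 1L
  if (in_window(p1 - left_start + 1L, config$length_range)) {
    out[[1L]] <- peptide_row(protein, left_start, p1, rule$name)
  }
  # right product starts at p1 + 1: peptide p1 + 1 .. first site >= p1 + 1
  right_end <- min(c(sites[sites > p1], L))
  if (in_window(right_end - p1, config$length_range)) {
    out[[length(out) + 1L]] <- peptide_row(protein, p1 + 1L, right_end,
                                           rule$name)
  }
  if (!length(out)) return(empty_peptides(rule$name))
  res <- do.call(rbind, out)
  res$planted_p1 <- rep(p1, nrow(res))
  res
}

planted_semi_peptides <- function(planted, protein, rule, config) {
  if (nrow(planted) == 0L) return(empty_peptides(rule$name))
  res <- lapply(planted$p1_pos, semi_at_site, protein = protein,
                rule = rule, config = config)
  do.call(rbind, res)
}

in_window <- function(len, range) len >= range[1L] && len <= range[2L]

peptide_row <- function(protein, start, end, wp) {
  L <- protein_length(protein)
  data.frame(
    protein_id = protein$id,
    peptide = substr(protein$sequence, start, end),
    prev_aa = if (start == 1L) "-" else
      substr(protein$sequence, start - 1L, start - 1L),
    next_aa = if (end == L) "-" else
      substr(protein$sequence, end + 1L, end + 1L),
    start = start, end = end, working_protease = wp, modifications = "",
    stringsAsFactors = FALSE)
}

empty_peptides <- function(wp) {
  data.frame(protein_id = character(), peptide = character(),
             prev_aa = character(), next_aa = character(),
             start = integer(), end = integer(),
             working_protease = character(), modifications = character(),
             planted_p1 = integer(), stringsAsFactors = FALSE)
}

# spurious semi peptides (in-source fragmentation / nonspecific
# proteolysis): truncate a theoretical peptide at a random internal
# position such that the new terminus is nonconforming; emitted
# symmetrically in both groups. Each theoretical peptide long enough to
# truncate spawns Poisson(background_semi_rate) spurious fragments.
background_semi <- function(fully, protein, rule, config) {
  out <- list()
  for (i in seq_len(nrow(fully))) {
    s <- fully$start[i]; e <- fully$end[i]
    len <- e - s + 1L
    if (len <= config$length_range[1L]) next
    n_spur <- stats::rpois(1L, config$background_semi_rate)
    for (spur in seq_len(n_spur)) {
      for (try in 1:10) {
        from_n <- stats::runif(1) < 0.5
        newlen <- sample(seq.int(config$length_range[1L], len - 1L), 1L)
        if (from_n) {
          ns <- e - newlen + 1L
          prev_res <- substr(protein$sequence, ns - 1L, ns - 1L)
          if (!(prev_res %in% rule$p1_residues)) {
            out[[length(out) + 1L]] <- peptide_row(protein, ns, e,
                                                   rule$name)
            break
          }
        } else {
          ne <- s + newlen - 1L
          last_res <- substr(protein$sequence, ne, ne)
          if (!(last_res %in% rule$p1_residues)) {
            out[[length(out) + 1L]] <- peptide_row(protein, s, ne,
                                                   rule$name)
            break
          }
        }
      }
    }
  }
  if (!length(out)) return(empty_peptides(rule$name)[, -9L])
  unique(do.call(rbind, out))
}

#' Run the full calling pipeline on one E/EQ experiment
#'
#' Classifies peptides per working protease, z-scores trypsin and GluC
#' digests separately, calls sites, and merges the per-protease calls at
#' the site level.
#'
#' @param obs Peptide observation table (both-group abundances required for
#'   z-scoring; single-group peptides are side-channelled).
#' @param enzyme Label for the protease under study.
#' @param z_threshold Significance threshold (default 2.0).
#' @param proteins Optional named list of [protein_record()]s.
#' @param corroborate_spanning Attach EQ-enriched fully specific spanning
#'   evidence (default TRUE).
#' @return List: `calls` (deduplicated `site_catalog`), `orphans`,
#'   `records` (classified, z-scored observations), `fences` (per working
#'   protease).
#' @export
call_experiment <- function(obs, enzyme = "enzyme", z_threshold = 2.0,
                            proteins = NULL, corroborate_spanning = TRUE) {
  per <- lapply(split(obs, obs$working_protease), function(block) {
    rule <- protease_rule(block$working_protease[1L])
    block <- classify_peptides(block, rule)
    block <- compute_ratios(block)
    block
  })
  records <- do.call(rbind, per)
  rownames(records) <- NULL
  fences <- lapply(per, function(block) abundance_fence(block$log2_abundance))
  calls_per <- lapply(names(per), function(wp) {
    call_sites(per[[wp]], enzyme = enzyme, z_threshold = z_threshold,
               fence = fences[[wp]], proteins = proteins)
  })
  calls <- deduplicate(do.call(rbind, calls_per))
  orphans <- NULL
  if (corroborate_spanning) {
    cor <- corroborate(calls, records, z_threshold = z_threshold)
    calls <- cor$calls
    orphans <- cor$orphans
  }
  list(calls = calls, orphans = orphans, records = records, fences = fences)
}

#' Precision/recall of calls against planted ground truth
#'
#' A call is a true positive iff its P1 position is planted. With no calls,
#' recall is 0 and precision is reported as 1 by convention with
#' `precision_defined = FALSE`.
#'
#' @param calls A `cleavage_calls` / `site_catalog` data.frame.
#' @param truth The `truth` element of a [simulate_experiment()] result (or
#'   any list with a `planted` data.frame).
#' @return List of class `recovery_report`: `precision`, `recall`,
#'   `precision_defined`, `n_calls`, `n_planted`, `detail` (per planted
#'   site: called or not), `false_positives`.
#' @export
recovery_report <- function(calls, truth) {
  planted <- truth$planted
  called_pos <- unique(as.data.frame(calls)$p1_pos)
  tp <- intersect(called_pos, planted$p1_pos)
  fp <- setdiff(called_pos, planted$p1_pos)
  n_calls <- length(called_pos)
  precision_defined <- n_calls > 0L
  structure(list(
    precision = if (precision_defined) length(tp) / n_calls else 1,
    recall = if (nrow(planted)) length(tp) / nrow(planted) else NA_real_,
    precision_defined = precision_defined,
    n_calls = n_calls, n_planted = nrow(planted),
    detail = data.frame(p1_pos = planted$p1_pos,
                        fraction = planted$fraction,
                        called = planted$p1_pos %in% called_pos),
    false_positives = fp),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report> recall %.3f (%d/%d), precision %.3f%s, %d calls\n",
    x$recall, sum(x$detail$called), x$n_planted, x$precision,
    if (!x$precision_defined) " (no calls; by convention)" else "",
    x$n_calls))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits the peptide TSV (merged E/EQ schema), substrate FASTA and ground
#' truth TSV into a directory.
#'
#' @param experiment A `synthetic_experiment`.
#' @param dir Output directory (created if needed).
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_peptide_table(experiment$observations,
                      file.path(dir, "peptides.tsv"))
  write_fasta(experiment$protein, file.path(dir, "protein.fasta"))
  utils::write.table(experiment$truth$planted,
                     file.path(dir, "truth_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(experiment$truth$provenance,
                     file.path(dir, "truth_provenance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
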