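# In-silico digestion and terminal-specificity classification.
#
# A working protease (trypsin or GluC) defines which peptide termini are
# "specific". A peptide with exactly one nonconforming terminus (semi-tryptic
# / semi-GluC) marks a candidate cleavage by the protease under study: the
# nonconforming terminus is the scissile bond, written P1-P1' in Schechter,
# Berger notation (P1 = residue N-terminal to the bond).

#' Working-protease cleavage rule
#'
#' Trypsin cleaves C-terminal to K/R and, by the conventional rule, not
#' before proline; GluC cleaves C-terminal to E/D with no blocked P1'
#' residue. Both residue sets are configurable.
#'
#' @param name `"trypsin"` or `"gluc"`.
#' @param p1_residues Residues after which the protease cleaves; defaults
#'   depend on `name`.
#' @param blocked_p1prime Residues that block cleavage when found in P1';
#'   default `"P"` for trypsin, none for GluC.
#' @return An object of class `protease_rule`.
#' @export
protease_rule <- function(name = c("trypsin", "gluc"),
                          p1_residues = NULL, blocked_p1prime = NULL) {
  name <- match.arg(name)
  if (is.null(p1_residues)) {
    p1_residues <- switch(name, trypsin = c("K", "R"), gluc = c("D", "E"))
  }
  if (is.null(blocked_p1prime)) {
    blocked_p1prime <- switch(name, trypsin = "P", gluc = character(0))
  }
  if (!length(p1_residues)) stop("p1_residues must be nonempty")
  structure(list(name = name, p1_residues = p1_residues,
                 blocked_p1prime = blocked_p1prime),
            class = "protease_rule")
}

#' Theoretical cleavage positions of a working protease
#'
#' @param protein A [protein_record()].
#' @param rule A [protease_rule()].
#' @param region Optional `c(start, end)` interval (1-based inclusive)
#'   restricting the scan.
#' @return Sorted integer vector of P1 positions `i` such that residue `i`
#'   is in the rule's P1 set, residue `i + 1` is not blocked, and
#'   `i < protein length`.
#' @export
theoretical_sites <- function(protein, rule, region = NULL) {
  stopifnot(inherits(protein, "protein_record"),
            inherits(rule, "protease_rule"))
  L <- protein_length(protein)
  if (is.null(region)) region <- c(1L, L)
  region <- as.integer(region)
  if (region[1L] > region[2L] || region[1L] < 1L || region[2L] > L) {
    stop("invalid region [", region[1L], ", ", region[2L], "]")
  }
  chars <- strsplit(protein$sequence, "")[[1]]
  idx <- seq.int(region[1L], region[2L])
  idx <- idx[idx < L]
  hits <- idx[chars[idx] %in% rule$p1_residues &
                !(chars[idx + 1L] %in% rule$blocked_p1prime)]
  as.integer(hits)
}

#' Digest a protein in silico
#'
#' Enumerates every fully specific peptide with at most `max_missed`
#' internal theoretical cleavage sites and length within `length_range`.
#' The zero-missed-cleavage peptide set tiles the full sequence exactly
#' once (before length filtering).
#'
#' @param protein A [protein_record()].
#' @param rule A [protease_rule()].
#' @param max_missed Maximum internal missed cleavages (default 2).
#' @param length_range `c(min, max)` peptide length window (default
#'   `c(6, 75)`, the usual LC-MS/MS detectability window).
#' @return A peptide observation data.frame (without abundances): columns
#'   `protein_id`, `peptide`, `prev_aa`, `next_aa`, `start`, `end`,
#'   `working_protease`, `modifications`, `n_missed`.
#' @export
digest_protein <- function(protein, rule, max_missed = 2L,
                           length_range = c(6L, 75L)) {
  stopifnot(inherits(protein, "protein_record"),
            inherits(rule, "protease_rule"),
            max_missed >= 0L, length_range[1L] <= length_range[2L])
  L <- protein_length(protein)
  sites <- theoretical_sites(protein, rule)
  bounds <- c(0L, sites, L)            # peptide k runs (bounds[i]+1)..bounds[j]
  n <- length(bounds)
  starts <- integer(0); ends <- integer(0); missed <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):min(n, i + 1L + max_missed)) {
      starts <- c(starts, bounds[i] + 1L)
      ends <- c(ends, bounds[j])
      missed <- c(missed, j - i - 1L)
    }
  }
  keep <- (ends - starts + 1L) >= length_range[1L] &
    (ends - starts + 1L) <= length_range[2L]
  starts <- starts[keep]; ends <- ends[keep]; missed <- missed[keep]
  data.frame(
    protein_id = rep(protein$id, length(starts)),
    peptide = substring(protein$sequence, starts, ends),
    prev_aa = ifelse(starts == 1L, "-",
                     substring(protein$sequence, starts - 1L, starts - 1L)),
    next_aa = ifelse(ends == L, "-",
                     substring(protein$sequence, ends + 1L, ends + 1L)),
    start = starts, end = ends,
    working_protease = rep(rule$name, length(starts)),
    modifications = rep("", length(starts)),
    n_missed = missed,
    stringsAsFactors = FALSE
  )
}

#' Classify peptide terminal specificity and infer candidate cleavage sites
#'
#' Each terminus is `specific` (conforms to the working-protease rule),
#' `nonspecific`, or `protein_terminus` (flank marker `-`, treated as
#' specific and yielding no site). The peptide class is `fully` when both
#' termini conform, `semi_n` / `semi_c` when exactly the N-/C-terminus is
#' nonspecific, and `nonspecific` otherwise. A semi peptide's nonconforming
#' terminus infers a site: `semi_n` gives P1 = `start - 1`, P1' = `start`;
#' `semi_c` gives P1 = `end`, P1' = `end + 1`. Modifications never alter the
#' classification.
#'
#' @param obs Peptide observation data.frame (see [read_peptide_table()]).
#' @param rule A [protease_rule()]; every row's `working_protease` must
#'   equal `rule$name`.
#' @param mature_start Optional 1-based position of a mature-protein start
#'   (e.g. after signal-peptide removal); when given, a peptide starting
#'   there counts as specific at its N-terminus. Default `NULL` (off).
#' @return `obs` with added columns `n_term_status`, `c_term_status`,
#'   `peptide_class`, `positionally_internal`, `p1_pos`, `p1prime_pos`.
#' @export
classify_peptides <- function(obs, rule, mature_start = NULL) {
  stopifnot(inherits(rule, "protease_rule"))
  if (nrow(obs) && !all(obs$working_protease == rule$name)) {
    stop("observations carry working_protease different from rule '",
         rule$name, "'")
  }
  first_res <- substr(obs$peptide, 1L, 1L)
  last_res <- substr(obs$peptide, nchar(obs$peptide), nchar(obs$peptide))

  n_status <- ifelse(
    obs$prev_aa == "-", "protein_terminus",
    ifelse(obs$prev_aa %in% rule$p1_residues &
             !(first_res %in% rule$blocked_p1prime),
           "specific", "nonspecific"))
  if (!is.null(mature_start)) {
    n_status[obs$start == mature_start & n_status == "nonspecific"] <-
      "protein_terminus"
  }
  c_status <- ifelse(
    obs$next_aa == "-", "protein_terminus",
    ifelse(last_res %in% rule$p1_residues &
             !(obs$next_aa %in% rule$blocked_p1prime),
           "specific", "nonspecific"))

  n_ok <- n_status %in% c("specific", "protein_terminus")
  c_ok <- c_status %in% c("specific", "protein_terminus")
  cls <- ifelse(n_ok & c_ok, "fully",
                ifelse(!n_ok & c_ok, "semi_n",
                       ifelse(n_ok & !c_ok, "semi_c", "nonspecific")))

  p1 <- ifelse(cls == "semi_n", obs$start - 1L,
               ifelse(cls == "semi_c", obs$end, NA_integer_))
  p1p <- ifelse(is.na(p1), NA_integer_, p1 + 1L)
  # The nonconforming terminus of a semi peptide is positionally internal
  # when it does not abut a protein terminus (P1 >= 2 keeps the scissile
  # bond away from position 1; the C-terminal side is guarded by next_aa).
  internal <- ifelse(cls == "semi_n", obs$prev_aa != "-" & p1 >= 2L,
                     ifelse(cls == "semi_c", obs$next_aa != "-", FALSE))

  obs$n_term_status <- n_status
  obs$c_term_status <- c_status
  obs$peptide_class <- cls
  obs$positionally_internal <- internal
  obs$p1_pos <- as.integer(p1)
  obs$p1prime_pos <- as.integer(p1p)
  obs
}

#' Sequence coverage of a peptide set
#'
#' @param peptides Peptide data.frame with `start`/`end` columns (rows for
#'   other proteins, by `protein_id`, are ignored).
#' @param protein A [protein_record()].
#' @return Fraction in `[0, 1]`: covered residues / protein length.
#' @export
coverage <- function(peptides, protein) {
  stopifnot(inherits(protein, "protein_record"))
  L <- protein_length(protein)
  if ("protein_id" %in% names(peptides)) {
    peptides <- peptides[peptides$protein_id == protein$id, , drop = FALSE]
  }
  if (nrow(peptides) == 0L) return(0)
  if (any(peptides$end > L | peptides$start < 1L)) {
    stop("peptide outside protein bounds")
  }
  mask <- logical(L)
  for (i in seq_len(nrow(peptides))) {
    mask[peptides$start[i]:peptides$end[i]] <- TRUE
  }
  sum(mask) / L
}

#' Cleavage-site density and residue scarcity within a region
#'
#' Reports the theoretical cleavage positions of a working protease inside a
#' region, the gaps between consecutive positions, and counts of selected
#' residues -- the quantities behind digestibility arguments such as "few
#' K/R residues in a chondroitin-sulfate domain imply long undigestible
#' stretches".
#'
#' @param protein A [protein_record()].
#' @param rule A [protease_rule()].
#' @param region `c(start, end)` interval; default full protein.
#' @param residues Residues to tally within the region; defaults to the
#'   rule's P1 set.
#' @return A list of class `density_report`: `region`, `n_sites`, `sites`,
#'   `gaps`, `mean_gap`, `max_gap`, `residue_counts`. With no sites in the
#'   region, `mean_gap` and `max_gap` equal the region length; with a single
#'   site no gap is defined and both are `NA`.
#' @export
site_density <- function(protein, rule, region = NULL,
                         residues = rule$p1_residues) {
  stopifnot(inherits(protein, "protein_record"),
            inherits(rule, "protease_rule"))
  L <- protein_length(protein)
  if (is.null(region)) region <- c(1L, L)
  region <- as.integer(region)
  if (region[1L] > region[2L] || region[1L] < 1L || region[2L] > L) {
    stop("invalid region [", region[1L], ", ", region[2L], "]")
  }
  region_len <- region[2L] - region[1L] + 1L
  sites <- theoretical_sites(protein, rule, region)
  gaps <- if (length(sites) >= 2L) diff(sites) else integer(0)
  if (length(sites) == 0L) {
    mean_gap <- region_len; max_gap <- region_len
  } else if (length(sites) == 1L) {
    mean_gap <- NA_real_; max_gap <- NA_real_
  } else {
    mean_gap <- mean(gaps); max_gap <- max(gaps)
  }
  chars <- strsplit(substr(protein$sequence, region[1L], region[2L]),
                    "")[[1]]
  counts <- vapply(residues, function(r) sum(chars == r), 0L)
  structure(list(region = region, n_sites = length(sites), sites = sites,
                 gaps = gaps, mean_gap = mean_gap, max_gap = max_gap,
                 residue_counts = counts),
            class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("<density_report> region %d-%d: %d sites, mean gap %s, max gap %s\n",
              x$region[1L], x$region[2L], x$n_sites,
              format(x$mean_gap), format(x$max_gap)))
  if (length(x$residue_counts)) {
    cat("  residue counts:",
        paste(names(x$residue_counts), x$residue_counts, sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}
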