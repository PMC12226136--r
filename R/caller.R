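# Two-step statistical identification of cleavage sites from an E/EQ
# experiment pair:
#   step 1 - z-scores on log2(E/EQ) abundance ratios over all peptides
#            quantified in both groups (trypsin and GluC digests are
#            z-scored separately);
#   step 2 - stratification of significant peptides by log2 abundance
#            against Tukey fences (Q1 - k*IQR, Q3 + k*IQR, k = 1.5).
# Semi-specific, positionally internal peptides with z at or above the
# threshold contribute candidate sites; fully specific peptides enriched in
# the inactive EQ control corroborate cleavage within their span.

#' Compute log2 E/EQ ratios and z-scores
#'
#' The z-score of a peptide is the number of standard deviations of its
#' log2(E/EQ) abundance ratio from the mean ratio of all peptides quantified
#' in both groups of the same digest (same working protease). Peptides found
#' in only one group are tagged `E_only` / `EQ_only`, excluded from the z
#' population, and reported with `z = NA`. The sample (n-1) standard
#' deviation is used.
#'
#' @param obs Peptide observation data.frame with `abundance_E`,
#'   `abundance_EQ`, `working_protease` columns.
#' @param abundance_from How the reference `log2_abundance` of a peptide is
#'   defined: `"enriched"` (default; log2 intensity of the more abundant
#'   group) or `"both"` (log2 of the mean of both groups).
#' @return `obs` with added columns `log2_abundance`, `log2_ratio`, `z`,
#'   `exclusive_group` (`NA`, `"E_only"` or `"EQ_only"`).
#' @export
compute_ratios <- function(obs, abundance_from = c("enriched", "both")) {
  abundance_from <- match.arg(abundance_from)
  if (any(obs$abundance_E <= 0 | obs$abundance_EQ <= 0, na.rm = TRUE)) {
    stop("abundances must be positive where present")
  }
  has_E <- !is.na(obs$abundance_E)
  has_EQ <- !is.na(obs$abundance_EQ)
  both <- has_E & has_EQ
  obs$exclusive_group <- ifelse(both, NA_character_,
                                ifelse(has_E, "E_only", "EQ_only"))
  obs$log2_ratio <- ifelse(both, log2(obs$abundance_E / obs$abundance_EQ),
                           NA_real_)
  obs$log2_abundance <- switch(
    abundance_from,
    enriched = log2(pmax(obs$abundance_E, obs$abundance_EQ, na.rm = TRUE)),
    both = log2((ifelse(has_E, obs$abundance_E, 0) +
                   ifelse(has_EQ, obs$abundance_EQ, 0)) /
                  (has_E + has_EQ))
  )
  obs$z <- NA_real_
  for (wp in unique(obs$working_protease)) {
    sel <- both & obs$working_protease == wp
    n <- sum(sel)
    if (n < 3L) {
      stop("fewer than 3 peptides quantified in both groups for '", wp, "'")
    }
    r <- obs$log2_ratio[sel]
    s <- stats::sd(r)
    if (s == 0) {
      stop("degenerate ratio distribution for '", wp,
           "': all log2 ratios identical")
    }
    obs$z[sel] <- (r - mean(r)) / s
  }
  obs
}

#' Tukey fences on log2 peptide abundance
#'
#' Quartiles are computed by linear interpolation of order statistics
#' (`stats::quantile` type 7); fences are `Q1 - k*IQR` and `Q3 + k*IQR`.
#'
#' @param log2_abundance Numeric vector of log2 abundances (>= 4 values),
#'   or a data.frame with a `log2_abundance` column.
#' @param k Fence multiplier (default 1.5).
#' @return List of class `fence_result`: `q1`, `q3`, `iqr`, `lower_fence`,
#'   `upper_fence`, `k`.
#' @export
abundance_fence <- function(log2_abundance, k = 1.5) {
  if (is.data.frame(log2_abundance)) {
    log2_abundance <- log2_abundance$log2_abundance
  }
  x <- log2_abundance[!is.na(log2_abundance)]
  if (length(x) < 4L) stop("need at least 4 abundances for fences")
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  structure(list(q1 = q[1L], q3 = q[2L], iqr = iqr,
                 lower_fence = q[1L] - k * iqr,
                 upper_fence = q[2L] + k * iqr, k = k),
            class = "fence_result")
}

#' @export
print.fence_result <- function(x, ...) {
  cat(sprintf(
    "<fence_result> Q1=%.3g Q3=%.3g IQR=%.3g fences [%.3g, %.3g] (k=%.2g)\n",
    x$q1, x$q3, x$iqr, x$lower_fence, x$upper_fence, x$k))
  invisible(x)
}

#' Call cleavage sites from significant semi-specific peptides
#'
#' A semi-specific, positionally internal peptide with `z >= z_threshold`
#' (E-enriched) contributes its inferred P1-P1' site. Peptides implying the
#' same `(protein_id, p1_pos)` are merged with pooled evidence. Each call is
#' tiered against the abundance fences by the maximum `log2_abundance` among
#' its semi evidence: `outlier_low` / `typical` / `outlier_high`.
#' Stratification never drops a call -- low-abundance significant peptides
#' are retained and flagged.
#'
#' @param records Data.frame combining the outputs of [compute_ratios()] and
#'   [classify_peptides()] on the same observations.
#' @param enzyme Label for the protease under study (e.g. `"ADAMTS9"`).
#' @param z_threshold Significance threshold on z (default 2.0).
#' @param fence Optional [abundance_fence()] result; when `NULL` it is
#'   computed from all co-quantified records.
#' @param proteins Optional named list of [protein_record()]s used to fill
#'   P1/P1' residue identities.
#' @return A data.frame of class `cleavage_calls`: one row per unique site
#'   with columns `protein_id`, `enzyme`, `p1_pos`, `p1_aa`, `p1prime_pos`,
#'   `p1prime_aa`, `n_semi_peptides`, `n_spanning_peptides`, `max_z`,
#'   `max_log2_abundance`, `tier`, `domain`, and a list-column
#'   `semi_evidence` of per-peptide evidence.
#' @export
call_sites <- function(records, enzyme = "enzyme", z_threshold = 2.0,
                       fence = NULL, proteins = NULL) {
  need <- c("peptide_class", "positionally_internal", "p1_pos", "z")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records lack column(s): ", paste(miss, collapse = ", "),
         " - run classify_peptides() and compute_ratios() first")
  }
  if (is.null(fence) && sum(!is.na(records$log2_abundance)) >= 4L) {
    fence <- abundance_fence(records$log2_abundance)
  }
  sig <- records[
    records$peptide_class %in% c("semi_n", "semi_c") &
      records$positionally_internal &
      !is.na(records$z) & records$z >= z_threshold, , drop = FALSE]
  build_calls(sig, enzyme, fence, proteins)
}

#' Build cleavage calls from classified semi-specific peptides
#'
#' Evidence-only variant of [call_sites()] for inputs whose significance
#' has already been established upstream (e.g. the packaged evidence
#' tables, which hold only peptides with significant z-scores): every
#' positionally internal semi-specific row contributes its inferred site,
#' with no z filtering. Rows of other classes are ignored.
#'
#' @inheritParams call_sites
#' @return A `cleavage_calls` data.frame, as for [call_sites()].
#' @export
calls_from_semi <- function(records, enzyme = "enzyme", fence = NULL,
                            proteins = NULL) {
  need <- c("peptide_class", "positionally_internal", "p1_pos")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records lack column(s): ", paste(miss, collapse = ", "),
         " - run classify_peptides() first")
  }
  if (!"z" %in% names(records)) {
    records$z <- rep(NA_real_, nrow(records))
  }
  sig <- records[records$peptide_class %in% c("semi_n", "semi_c") &
                   records$positionally_internal, , drop = FALSE]
  build_calls(sig, enzyme, fence, proteins)
}

build_calls <- function(sig, enzyme, fence, proteins) {
  if (nrow(sig) == 0L) return(empty_calls())
  if (!"log2_abundance" %in% names(sig)) sig$log2_abundance <- NA_real_
  key <- paste(sig$protein_id, sig$p1_pos, sep = "\r")
  groups <- split(seq_len(nrow(sig)), key)
  rows <- lapply(groups, function(idx) {
    g <- sig[idx, , drop = FALSE]
    max_ab <- suppressWarnings(max(g$log2_abundance, na.rm = TRUE))
    if (!is.finite(max_ab)) max_ab <- NA_real_
    data.frame(
      protein_id = g$protein_id[1L], enzyme = enzyme,
      p1_pos = g$p1_pos[1L],
      p1_aa = site_residue(proteins, g$protein_id[1L], g$p1_pos[1L], g),
      p1prime_pos = g$p1_pos[1L] + 1L,
      p1prime_aa = site_residue(proteins, g$protein_id[1L],
                                g$p1_pos[1L] + 1L, g),
      n_semi_peptides = nrow(g), n_spanning_peptides = 0L,
      max_z = max_or_na(g$z), max_log2_abundance = max_ab,
      tier = tier_of(max_ab, fence), domain = NA_character_,
      stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  calls$semi_evidence <- lapply(groups, function(idx) {
    sig[idx, intersect(c("peptide", "prev_aa", "next_aa", "start", "end",
                         "working_protease", "modifications", "z",
                         "log2_abundance"), names(sig)), drop = FALSE]
  })
  calls$spanning_evidence <- rep(list(NULL), nrow(calls))
  calls <- calls[order(calls$protein_id, calls$p1_pos), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("cleavage_calls", class(calls))
  calls
}

max_or_na <- function(x) {
  if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
}

empty_calls <- function() {
  calls <- data.frame(
    protein_id = character(), enzyme = character(), p1_pos = integer(),
    p1_aa = character(), p1prime_pos = integer(), p1prime_aa = character(),
    n_semi_peptides = integer(), n_spanning_peptides = integer(),
    max_z = numeric(), max_log2_abundance = numeric(), tier = character(),
    domain = character(), stringsAsFactors = FALSE)
  calls$semi_evidence <- list()
  calls$spanning_evidence <- list()
  class(calls) <- c("cleavage_calls", class(calls))
  calls
}

tier_of <- function(log2_ab, fence) {
  if (is.null(fence) || is.na(log2_ab)) return(NA_character_)
  if (log2_ab < fence$lower_fence) "outlier_low"
  else if (log2_ab > fence$upper_fence) "outlier_high"
  else "typical"
}

# P1/P1' residue identity: from the protein sequence when available,
# otherwise reconstructed from the evidence peptide and its flanks.
site_residue <- function(proteins, protein_id, pos, evidence) {
  p <- if (!is.null(proteins)) proteins[[protein_id]] else NULL
  if (!is.null(p) && pos >= 1L && pos <= protein_length(p)) {
    res <- substr(p$sequence, pos, pos)
    if (res != "X") return(res)
  }
  for (i in seq_len(nrow(evidence))) {
    s <- evidence$start[i]; e <- evidence$end[i]
    if (pos >= s && pos <= e) {
      return(substr(evidence$peptide[i], pos - s + 1L, pos - s + 1L))
    }
    if (pos == s - 1L) return(evidence$prev_aa[i])
    if (pos == e + 1L) return(evidence$next_aa[i])
  }
  NA_character_
}

#' Corroborate calls with EQ-enriched fully specific spanning peptides
#'
#' A fully specific peptide significantly enriched in the inactive EQ
#' control (`z <= -z_threshold`) whose interval contains a called site's P1
#' position strictly inside it attaches to that call as spanning evidence
#' (the intact stretch is depleted in the active digest because it is being
#' cut). EQ-enriched spanners covering no call are returned as orphan
#' signals: candidate cleavage regions with no semi-specific support.
#'
#' @param calls A `cleavage_calls` data.frame from [call_sites()].
#' @param records Classified, z-scored records (the fully specific rows are
#'   used; other rows are ignored).
#' @param z_threshold Significance threshold (default 2.0).
#' @return List with elements `calls` (augmented) and `orphans` (data.frame
#'   of unexplained EQ-enriched spanning peptides).
#' @export
corroborate <- function(calls, records, z_threshold = 2.0) {
  fully <- records[records$peptide_class == "fully" & !is.na(records$z) &
                     records$z <= -z_threshold, , drop = FALSE]
  orphan_idx <- integer(0)
  if (nrow(fully)) {
    for (i in seq_len(nrow(fully))) {
      hit <- which(calls$protein_id == fully$protein_id[i] &
                     calls$p1_pos > fully$start[i] &
                     calls$p1_pos < fully$end[i])
      if (length(hit)) {
        for (h in hit) {
          ev <- fully[i, intersect(c("peptide", "start", "end",
                                     "working_protease", "z",
                                     "log2_abundance"), names(fully)),
                      drop = FALSE]
          calls$spanning_evidence[[h]] <-
            rbind(calls$spanning_evidence[[h]], ev)
          calls$n_spanning_peptides[h] <- calls$n_spanning_peptides[h] + 1L
        }
      } else {
        orphan_idx <- c(orphan_idx, i)
      }
    }
  }
  orphans <- fully[orphan_idx, , drop = FALSE]
  rownames(orphans) <- NULL
  list(calls = calls, orphans = orphans)
}

#' Write a site table
#'
#' @param calls A `cleavage_calls` or site-catalog data.frame.
#' @param path Output path (TSV).
#' @export
write_site_table <- function(calls, path) {
  cols <- c("protein_id", "enzyme", "p1_pos", "p1_aa", "p1prime_pos",
            "p1prime_aa", "domain", "n_semi_peptides",
            "n_spanning_peptides", "max_z", "tier")
  out <- as.data.frame(calls)[, intersect(cols, names(calls)), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
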