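# IceLogo-style subsite specificity analysis: P5..P1 / P1'..P5' windows
# around cleavage sites, scored as percentage differences between the
# observed residue frequency at each subsite and a reference proteome
# composition, with per-cell significance from a normal approximation to
# the reference proportion.

LOGO_POSITIONS <- c("P5", "P4", "P3", "P2", "P1",
                    "P1p", "P2p", "P3p", "P4p", "P5p")

#' Extract P5-P5' windows around cleavage sites
#'
#' @param sites Data.frame with `protein_id` and `p1_pos` columns (e.g. a
#'   `site_catalog`).
#' @param proteins Named list of [protein_record()]s covering every
#'   `protein_id`.
#' @param span Number of subsites on each side of the scissile bond
#'   (default 5).
#' @return Character matrix, one row per site, columns `P<span>`..`P1`,
#'   `P1p`..`P<span>p`. Slots beyond a protein terminus carry the padding
#'   marker `"-"`; slots of unknown residue identity carry `"X"`. The P1
#'   column always equals the protein residue at `p1_pos`.
#' @export
extract_windows <- function(sites, proteins, span = 5L) {
  stopifnot(span >= 1L)
  cols <- c(paste0("P", span:1), paste0("P", 1:span, "p"))
  win <- matrix("-", nrow = nrow(sites), ncol = 2L * span,
                dimnames = list(NULL, cols))
  for (i in seq_len(nrow(sites))) {
    p <- proteins[[sites$protein_id[i]]]
    if (is.null(p)) stop("no protein record for ", sites$protein_id[i])
    L <- protein_length(p)
    p1 <- sites$p1_pos[i]
    if (p1 < 1L || p1 >= L) stop("site ", p1, " outside ", p$id)
    offs <- c(-(span:1) + 1L, 1:span)   # residue = p1 + off for each column
    pos <- p1 + offs
    ok <- pos >= 1L & pos <= L
    win[i, ok] <- vapply(pos[ok], function(j) substr(p$sequence, j, j), "")
  }
  win
}

#' Read a reference amino-acid composition
#'
#' @param path TSV with columns `residue`, `percent`; percentages must sum
#'   to 100 (tolerance 0.1). When `path` is missing, the packaged human
#'   proteome-average composition is used.
#' @return Named numeric vector over the 20 standard residues (percent).
#' @export
read_reference_composition <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_composition_human.tsv",
                        package = "cleavemap", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  stopifnot(all(c("residue", "percent") %in% names(tab)))
  ref <- stats::setNames(as.numeric(tab$percent), tab$residue)
  miss <- setdiff(AA_ALPHABET, names(ref))
  if (length(miss)) stop("reference composition missing residue(s): ",
                         paste(miss, collapse = ", "))
  ref <- ref[AA_ALPHABET]
  if (abs(sum(ref) - 100) > 0.1) {
    stop("reference composition sums to ", format(sum(ref)), ", not 100")
  }
  ref
}

#' Percentage-difference logo scores
#'
#' For each subsite position and residue, compares the observed frequency
#' percentage among the windows with the reference composition. Padding
#' (`-`) and unknown (`X`) slots are excluded from that position's
#' denominator, keeping percentages comparable with the reference set.
#' Significance per cell is a two-sided z-test of the observed proportion
#' against the reference proportion p0 with standard deviation
#' sqrt(p0 (1 - p0) / n), n being the number of informative slots at that
#' position.
#'
#' @param windows Character matrix from [extract_windows()].
#' @param reference Named percent vector from
#'   [read_reference_composition()]; default the packaged human set.
#' @param p Two-sided significance level (default 0.05).
#' @return Data.frame of class `logo_matrix`: `position`, `residue`,
#'   `observed_pct`, `reference_pct`, `diff`, `z`, `significant`, `n`.
#'   Within each position the `diff` column sums to zero.
#' @export
logo_scores <- function(windows, reference = read_reference_composition(),
                        p = 0.05) {
  if (nrow(windows) == 0L) stop("empty window set")
  zcrit <- stats::qnorm(1 - p / 2)
  out <- do.call(rbind, lapply(colnames(windows), function(col) {
    slot <- windows[, col]
    slot <- slot[slot %in% AA_ALPHABET]
    n <- length(slot)
    obs_pct <- if (n) {
      100 * vapply(AA_ALPHABET, function(r) sum(slot == r), 0L) / n
    } else {
      stats::setNames(rep(NA_real_, length(AA_ALPHABET)), AA_ALPHABET)
    }
    # renormalise the reference to exactly 100 so that both columns are
    # proper percentages over the 20 residues and sum(diff) == 0.
    ref_pct <- 100 * reference[AA_ALPHABET] / sum(reference[AA_ALPHABET])
    z <- if (n) {
      (obs_pct / 100 - ref_pct / 100) /
        sqrt((ref_pct / 100) * (1 - ref_pct / 100) / n)
    } else rep(NA_real_, length(AA_ALPHABET))
    data.frame(position = col, residue = AA_ALPHABET,
               observed_pct = as.numeric(obs_pct),
               reference_pct = as.numeric(ref_pct),
               diff = as.numeric(obs_pct - ref_pct),
               z = as.numeric(z),
               significant = !is.na(z) & abs(z) >= zcrit,
               n = n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$position <- factor(out$position, levels = colnames(windows))
  class(out) <- c("logo_matrix", class(out))
  out
}

#' Write a logo matrix as TSV
#' @param logo A `logo_matrix`.
#' @param path Output path.
#' @export
write_logo_matrix <- function(logo, path) {
  utils::write.table(as.data.frame(logo), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
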