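# Site-level bookkeeping across substrates and enzymes: deduplication,
# domain annotation, cross-enzyme sharing, novelty against known-site
# lists, and isoform position mapping. Site identity across enzymes is the
# P1 position on the same protein isoform; cross-isoform identity always
# goes through an explicit position map (isoform numbering differs and
# silent renumbering is the main error mode).

#' Deduplicate cleavage calls into a site catalog
#'
#' Merges calls sharing `(protein_id, p1_pos, enzyme)`, pooling evidence
#' counts and taking the maximum z. Idempotent.
#'
#' @param calls A `cleavage_calls` data.frame (rows from one or more
#'   [call_sites()] runs, possibly concatenated across experiments).
#' @return A data.frame of class `site_catalog` keyed by
#'   `(protein_id, p1_pos, enzyme)`.
#' @export
deduplicate <- function(calls) {
  calls <- as.data.frame(calls)
  if (nrow(calls) == 0L) {
    out <- empty_calls()
    class(out) <- c("site_catalog", class(out))
    return(out)
  }
  key <- paste(calls$protein_id, calls$p1_pos, calls$enzyme, sep = "\r")
  groups <- split(seq_len(nrow(calls)), key)
  rows <- lapply(groups, function(idx) {
    g <- calls[idx, , drop = FALSE]
    out <- g[1L, , drop = FALSE]
    out$n_semi_peptides <- sum(g$n_semi_peptides)
    out$n_spanning_peptides <- sum(g$n_spanning_peptides)
    out$max_z <- max_or_na(g$max_z)
    if ("max_log2_abundance" %in% names(g)) {
      out$max_log2_abundance <- suppressWarnings(
        max(g$max_log2_abundance, na.rm = TRUE))
      if (!is.finite(out$max_log2_abundance)) {
        out$max_log2_abundance <- NA_real_
      }
    }
    if ("semi_evidence" %in% names(g)) {
      out$semi_evidence <- list(do.call(rbind, g$semi_evidence))
    }
    if ("spanning_evidence" %in% names(g)) {
      sp <- g$spanning_evidence[!vapply(g$spanning_evidence, is.null, TRUE)]
      out$spanning_evidence <- list(if (length(sp)) do.call(rbind, sp))
    }
    out
  })
  cat_df <- do.call(rbind, rows)
  cat_df <- cat_df[order(cat_df$protein_id, cat_df$p1_pos, cat_df$enzyme), ,
                   drop = FALSE]
  rownames(cat_df) <- NULL
  class(cat_df) <- unique(c("site_catalog", "cleavage_calls",
                            class(cat_df)))
  cat_df
}

#' Annotate catalog entries with protein domains
#'
#' Each site's P1 position is mapped to the first containing interval in
#' domain-table order; positions covered by no interval are labelled
#' `"interdomain"`.
#'
#' @param catalog A `site_catalog` or `cleavage_calls` data.frame.
#' @param domains Domain table: data.frame with `protein_id`, `name`,
#'   `start`, `end` (see [read_domain_table()]).
#' @return The catalog with its `domain` column filled.
#' @export
annotate_domains <- function(catalog, domains) {
  stopifnot(all(c("protein_id", "name", "start", "end") %in% names(domains)))
  if (nrow(catalog) == 0L) return(catalog)
  catalog$domain <- vapply(seq_len(nrow(catalog)), function(i) {
    d <- domains[domains$protein_id == catalog$protein_id[i], , drop = FALSE]
    hit <- which(d$start <= catalog$p1_pos[i] & catalog$p1_pos[i] <= d$end)
    if (length(hit)) d$name[hit[1L]] else "interdomain"
  }, "")
  catalog
}

#' Cross-enzyme sharing of cleavage sites on one substrate
#'
#' @param catalogs A list of `site_catalog`s (one per enzyme), or a single
#'   catalog holding several enzymes; all entries must be on the same
#'   substrate protein.
#' @return List of class `sharing_report`: `positions` (data.frame with
#'   `p1_pos` and comma-joined `enzymes`, `n_enzymes`), `shared` (positions
#'   called by >= 2 enzymes), `exclusive` (named counts of single-enzyme
#'   sites per enzyme), `union_size`.
#' @export
compare_enzymes <- function(catalogs) {
  combined <- bind_catalogs(catalogs)
  if (length(unique(combined$protein_id)) > 1L) {
    stop("compare_enzymes requires catalogs on a single substrate; got: ",
         paste(unique(combined$protein_id), collapse = ", "))
  }
  by_pos <- split(combined$enzyme, combined$p1_pos)
  positions <- data.frame(
    p1_pos = as.integer(names(by_pos)),
    enzymes = vapply(by_pos, function(e)
      paste(sort(unique(e)), collapse = ","), ""),
    n_enzymes = vapply(by_pos, function(e) length(unique(e)), 0L),
    stringsAsFactors = FALSE)
  positions <- positions[order(positions$p1_pos), , drop = FALSE]
  rownames(positions) <- NULL
  shared <- positions$p1_pos[positions$n_enzymes >= 2L]
  excl <- positions[positions$n_enzymes == 1L, , drop = FALSE]
  exclusive <- table(excl$enzymes)
  structure(list(positions = positions, shared = shared,
                 exclusive = c(exclusive), union_size = nrow(positions)),
            class = "sharing_report")
}

#' @export
print.sharing_report <- function(x, ...) {
  cat(sprintf(
    "<sharing_report> %d unique positions (%d shared by >=2 enzymes)\n",
    x$union_size, length(x$shared)))
  if (length(x$exclusive)) {
    cat("  exclusive:", paste(names(x$exclusive), x$exclusive, sep = "=",
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Shared positions between two enzymes
#'
#' @param report A `sharing_report`.
#' @param enzyme_a,enzyme_b Enzyme labels.
#' @return Integer vector of P1 positions called by both enzymes.
#' @export
shared_between <- function(report, enzyme_a, enzyme_b) {
  pos <- report$positions
  sets <- strsplit(pos$enzymes, ",", fixed = TRUE)
  hit <- vapply(sets, function(s) enzyme_a %in% s && enzyme_b %in% s, TRUE)
  pos$p1_pos[hit]
}

#' Union of site positions across catalogs and novelty against known sites
#'
#' @param catalogs A list of catalogs or one combined catalog.
#' @param known_sites Optional data.frame with `protein_id` and `p1_pos`
#'   columns (known cleavage sites on the same residue numbering).
#' @return List: `union_positions` (data.frame `protein_id`, `p1_pos`),
#'   `union_size`, `novel_positions`, `n_novel`.
#' @export
union_novel <- function(catalogs, known_sites = NULL) {
  combined <- bind_catalogs(catalogs)
  uni <- unique(combined[, c("protein_id", "p1_pos"), drop = FALSE])
  uni <- uni[order(uni$protein_id, uni$p1_pos), , drop = FALSE]
  rownames(uni) <- NULL
  if (is.null(known_sites) || nrow(known_sites) == 0L) {
    novel <- uni
  } else {
    known_key <- paste(known_sites$protein_id, known_sites$p1_pos)
    novel <- uni[!(paste(uni$protein_id, uni$p1_pos) %in% known_key), ,
                 drop = FALSE]
  }
  rownames(novel) <- NULL
  list(union_positions = uni, union_size = nrow(uni),
       novel_positions = novel, n_novel = nrow(novel))
}

bind_catalogs <- function(catalogs) {
  if (is.data.frame(catalogs)) catalogs <- list(catalogs)
  core <- lapply(catalogs, function(x)
    as.data.frame(x)[, c("protein_id", "p1_pos", "enzyme"), drop = FALSE])
  combined <- do.call(rbind, core)
  unique(combined)
}

#' Map a residue position between isoforms
#'
#' Uses an explicit pairwise correspondence map of aligned blocks; positions
#' are never inferred by local alignment. The packaged versican V1/V2 map
#' (see `system.file("extdata", "isoform_map_versican.tsv", package =
#' "cleavemap")`) encodes the shared G1 block and the G3-side block whose
#' offset is anchored by the corresponding cleavage positions printed for
#' the two isoforms.
#'
#' @param pos Position in the source isoform.
#' @param map Data.frame with columns `protein_a`, `start_a`, `end_a`,
#'   `protein_b`, `start_b`: block `start_a..end_a` of isoform a aligns
#'   gaplessly to the block beginning at `start_b` of isoform b.
#' @param from,to Isoform identifiers (must match `protein_a`/`protein_b`;
#'   the map is usable in both directions).
#' @return Mapped integer position in the target isoform.
#' @export
map_isoform_position <- function(pos, map, from, to) {
  stopifnot(all(c("protein_a", "start_a", "end_a", "protein_b", "start_b")
                %in% names(map)))
  if (from == to) return(as.integer(pos))
  fwd <- map[map$protein_a == from & map$protein_b == to, , drop = FALSE]
  hit <- which(fwd$start_a <= pos & pos <= fwd$end_a)
  if (length(hit)) {
    b <- fwd[hit[1L], ]
    return(as.integer(b$start_b + (pos - b$start_a)))
  }
  rev <- map[map$protein_a == to & map$protein_b == from, , drop = FALSE]
  if (nrow(rev)) {
    end_b <- rev$start_b + (rev$end_a - rev$start_a)
    hit <- which(rev$start_b <= pos & pos <= end_b)
    if (length(hit)) {
      b <- rev[hit[1L], ]
      return(as.integer(b$start_a + (pos - b$start_b)))
    }
  }
  stop("position ", pos, " of ", from, " is not covered by the ", from,
       "/", to, " correspondence map")
}

#' Read an isoform correspondence map
#' @param path TSV with columns `protein_a`, `start_a`, `end_a`,
#'   `protein_b`, `start_b`.
#' @export
read_isoform_map <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  need <- c("protein_a", "start_a", "end_a", "protein_b", "start_b")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("map lacks column(s): ",
                         paste(miss, collapse = ", "))
  tab$start_a <- as.integer(tab$start_a)
  tab$end_a <- as.integer(tab$end_a)
  tab$start_b <- as.integer(tab$start_b)
  tab
}
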