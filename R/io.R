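# Readers/writers for the external formats touched by the pipeline:
# protein FASTA, peptide quantification tables (TSV), domain tables (TSV).
# Coordinates are 1-based inclusive throughout, matching UniProt residue
# numbering as used in cleavage-site labels such as "E441-A442".

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")
# "X" marks residues of unknown identity (e.g. scaffold filler); it is never
# a cleavage-rule residue and is treated as missing in composition counts.
AA_ALPHABET_X <- c(AA_ALPHABET, "X")

PEPTIDE_TABLE_COLUMNS <- c("protein_id", "peptide", "prev_aa", "next_aa",
                           "start", "end", "working_protease",
                           "modifications", "abundance_E", "abundance_EQ")

#' Construct a protein record
#'
#' A protein record bundles an identifier (typically a UniProt isoform
#' accession), the amino-acid sequence in 1-based residue numbering, a
#' free-text description, and an optional domain annotation table.
#'
#' @param id Character identifier, e.g. `"P21810"`.
#' @param sequence Amino-acid string (uppercased); alphabet restricted to the
#'   20 standard residues plus `X`.
#' @param description Optional free text.
#' @param domains Optional data.frame with columns `name`, `start`, `end`
#'   (1-based inclusive); intervals may nest or overlap, lookups are resolved
#'   by first match in table order.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, description = "", domains = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (!nzchar(sequence)) {
    stop("protein ", id, ": empty sequence")
  }
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), AA_ALPHABET_X)
  if (length(bad)) {
    stop("protein ", id, ": illegal residue(s) ", paste(bad, collapse = ", "))
  }
  if (!is.null(domains)) {
    domains <- validate_domains(domains, nchar(sequence), id)
  }
  structure(
    list(id = id, sequence = sequence, description = description,
         domains = domains),
    class = "protein_record"
  )
}

validate_domains <- function(domains, protein_length, id = "?") {
  stopifnot(is.data.frame(domains))
  need <- c("name", "start", "end")
  if (!all(need %in% names(domains))) {
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  }
  domains$start <- as.integer(domains$start)
  domains$end <- as.integer(domains$end)
  if (any(domains$start > domains$end)) {
    stop("protein ", id, ": domain with start > end")
  }
  if (any(domains$start < 1L) || any(domains$end > protein_length)) {
    stop("protein ", id, ": domain interval outside [1, ", protein_length, "]")
  }
  domains
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)%s\n", x$id, nchar(x$sequence),
              if (nzchar(x$description)) paste0(" - ", x$description) else ""))
  invisible(x)
}

#' Length of a protein record
#' @param x A `protein_record`.
#' @export
protein_length <- function(x) {
  stopifnot(inherits(x, "protein_record"))
  nchar(x$sequence)
}

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased and whitespace-stripped; each entry must use only
#' the 20 standard residues plus `X`. The first whitespace-delimited token of
#' the header is the record id, the remainder its description.
#'
#' @param path Path to a FASTA file.
#' @return A named list of [protein_record()] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA '", path, "' contains no entries")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  recs <- lapply(seq_along(set), function(i) {
    protein_record(ids[i], as.character(set[[i]]), descs[i])
  })
  names(recs) <- ids
  recs
}

#' Write protein records to FASTA
#' @param proteins A list of [protein_record()] objects.
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  if (inherits(proteins, "protein_record")) proteins <- list(proteins)
  seqs <- Biostrings::AAStringSet(vapply(proteins, `[[`, "", "sequence"))
  names(seqs) <- vapply(proteins, function(p) {
    if (nzchar(p$description)) paste(p$id, p$description) else p$id
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a peptide quantification table
#'
#' Tab-separated, UTF-8, with required columns `protein_id`, `peptide`,
#' `prev_aa`, `next_aa`, `start`, `end`, `working_protease`, `modifications`
#' (semicolon-joined `pos:label`, empty allowed), `abundance_E`,
#' `abundance_EQ`. An empty abundance cell means the peptide was not
#' quantified in that group and is read as `NA`, never as zero. Extra columns
#' are carried along untouched.
#'
#' @param path Path to the TSV file.
#' @param proteins Optional named list of [protein_record()]s; when supplied,
#'   each row's sequence, positions and flanking residues are checked against
#'   the protein sequence.
#' @return A data.frame of peptide observations.
#' @export
read_peptide_table <- function(path, proteins = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(PEPTIDE_TABLE_COLUMNS, names(tab))
  if (length(missing_cols)) {
    stop("peptide table '", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0L) return(coerce_peptide_types(tab))
  tab <- coerce_peptide_types(tab)
  validate_observations(tab, proteins)
  tab
}

coerce_peptide_types <- function(tab) {
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab$abundance_E <- suppressWarnings(
    as.numeric(ifelse(tab$abundance_E == "", NA, tab$abundance_E)))
  tab$abundance_EQ <- suppressWarnings(
    as.numeric(ifelse(tab$abundance_EQ == "", NA, tab$abundance_EQ)))
  tab
}

#' Validate peptide observations
#'
#' Checks the structural invariants of a peptide table: positive lengths
#' consistent with coordinates, flank/terminus markers, nonnegative
#' abundances with at least one group quantified, and (when protein records
#' are supplied) agreement of sequence and flanks with the protein.
#' Scaffold positions of unknown identity (`X`) are not compared.
#'
#' @param obs Peptide observation data.frame.
#' @param proteins Optional named list of [protein_record()]s.
#' @return Invisibly, `obs`.
#' @export
validate_observations <- function(obs, proteins = NULL) {
  if (nrow(obs) == 0L) return(invisible(obs))
  len <- nchar(obs$peptide)
  bad <- which(obs$end - obs$start + 1L != len)
  if (length(bad)) {
    stop("row ", bad[1L], ": peptide length ", len[bad[1L]],
         " inconsistent with positions ", obs$start[bad[1L]], "-",
         obs$end[bad[1L]])
  }
  if (any(obs$start < 1L)) stop("peptide start before position 1")
  neg <- which(obs$abundance_E < 0 | obs$abundance_EQ < 0)
  if (length(neg)) stop("row ", neg[1L], ": negative abundance")
  none <- which(is.na(obs$abundance_E) & is.na(obs$abundance_EQ))
  if (length(none)) stop("row ", none[1L], ": no abundance in either group")
  if (!all(obs$working_protease %in% c("trypsin", "gluc"))) {
    stop("working_protease must be 'trypsin' or 'gluc'")
  }
  if (!is.null(proteins)) {
    for (i in seq_len(nrow(obs))) {
      p <- proteins[[obs$protein_id[i]]]
      if (is.null(p)) next
      L <- protein_length(p)
      if (obs$end[i] > L) {
        stop("row ", i, ": peptide extends beyond ", p$id, " (", L, " aa)")
      }
      sub <- substr(p$sequence, obs$start[i], obs$end[i])
      if (!seq_matches(obs$peptide[i], sub)) {
        stop("row ", i, ": peptide '", obs$peptide[i],
             "' does not match ", p$id, " at ", obs$start[i], "-", obs$end[i])
      }
      exp_prev <- if (obs$start[i] == 1L) "-" else
        substr(p$sequence, obs$start[i] - 1L, obs$start[i] - 1L)
      exp_next <- if (obs$end[i] == L) "-" else
        substr(p$sequence, obs$end[i] + 1L, obs$end[i] + 1L)
      if (!flank_matches(obs$prev_aa[i], exp_prev) ||
          !flank_matches(obs$next_aa[i], exp_next)) {
        stop("row ", i, ": flanks [", obs$prev_aa[i], "]/[", obs$next_aa[i],
             "] inconsistent with ", p$id, " (expected [", exp_prev, "]/[",
             exp_next, "])")
      }
    } }
  invisible(obs)
}

seq_matches <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb)) return(FALSE)
  all(ca == cb | ca == "X" | cb == "X")
}

flank_matches <- function(a, b) a == b || a == "X" || b == "X"

#' Write a peptide table
#'
#' Inverse of [read_peptide_table()]: fields round-trip identically,
#' absent abundances are written as empty cells.
#'
#' @param obs Peptide observation data.frame.
#' @param path Output path.
#' @export
write_peptide_table <- function(obs, path) {
  out <- obs
  out$abundance_E <- ifelse(is.na(out$abundance_E), "",
                            format(out$abundance_E, trim = TRUE,
                                   scientific = FALSE, digits = 15))
  out$abundance_EQ <- ifelse(is.na(out$abundance_EQ), "",
                             format(out$abundance_EQ, trim = TRUE,
                                    scientific = FALSE, digits = 15))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a domain annotation table
#'
#' Tab-separated with columns `protein_id`, `domain_name`, `start`, `end`
#' (1-based inclusive). Intervals may nest; lookups use the first containing
#' interval in file order.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `protein_id`, `name`, `start`, `end`.
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  need <- c("protein_id", "domain_name", "start", "end")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("domain table lacks column(s): ", paste(miss, collapse = ", "))
  }
  data.frame(protein_id = tab$protein_id, name = tab$domain_name,
             start = as.integer(tab$start), end = as.integer(tab$end),
             stringsAsFactors = FALSE)
}

#' Parse a modifications field
#'
#' @param x Character vector of semicolon-joined `pos:label` entries
#'   (empty string = no modifications).
#' @return A list (one element per input) of data.frames with columns
#'   `position` and `label`.
#' @export
parse_modifications <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(data.frame(position = integer(), label = character(),
                        stringsAsFactors = FALSE))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    pos <- vapply(parts, function(p) as.integer(p[1L]), 0L)
    lab <- vapply(parts, function(p) p[2L], "")
    bad <- setdiff(lab, c("acetyl", "oxidation", "pyroglu"))
    if (length(bad)) stop("unknown modification label(s): ",
                          paste(bad, collapse = ", "))
    data.frame(position = pos, label = lab, stringsAsFactors = FALSE)
  })
}
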