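# Packaged worked-example fixtures: the peptide evidence tables for the
# ADAMTS9 MDTCS autolysis digest (Table1), the versican V1 (Table2) and V2
# (Table3, Table4) digests, and the biglycan digests (Table5), together
# with synthetic scaffold protein sequences, domain interval tables and the
# versican V1/V2 correspondence map.
#
# The scaffold sequences are synthetic: they carry the residues evidenced
# by the fixture peptides and their flanks at the published coordinates and
# `X` elsewhere. Domain boundaries are reverse-engineered from the
# published domain labels (the labels are printed, the intervals are not)
# and the tables' printed log2 abundance / z values ride along as reference
# metadata only -- the pipeline never consumes them as inputs.

FIXTURE_SOURCES <- c("Table1", "Table2", "Table3", "Table4", "Table5")

fixture_path <- function(file) {
  system.file("extdata", file, package = "cleavemap", mustWork = TRUE)
}

#' Load a packaged peptide evidence table
#'
#' @param source One of `"Table1"` .. `"Table5"`.
#' @param enzyme Optional enzyme label (`"ADAMTS1"`, `"ADAMTS4"`,
#'   `"ADAMTS5"`, `"ADAMTS9"`) to subset multi-enzyme tables.
#' @param row_class Optional subset: `"semi"` (candidate-site evidence) or
#'   `"spanning"` (fully specific peptides enriched in the EQ control).
#' @return A peptide observation data.frame with additional columns
#'   `enzyme`, `source`, `row_class`, `paper_p1_pos`, `paper_site`,
#'   `paper_domain`, `paper_log2_abundance`, `paper_z`, `eq_higher`.
#' @export
load_fixture <- function(source, enzyme = NULL, row_class = NULL) {
  if (!source %in% FIXTURE_SOURCES) {
    stop("unknown fixture '", source, "'; expected one of ",
         paste(FIXTURE_SOURCES, collapse = ", "))
  }
  tab <- read_peptide_table(
    fixture_path(sprintf("peptides_%s.tsv", tolower(source))))
  tab$paper_p1_pos <- suppressWarnings(as.integer(tab$paper_p1_pos))
  tab$paper_log2_abundance <- as.numeric(tab$paper_log2_abundance)
  tab$paper_z <- as.numeric(tab$paper_z)
  tab$eq_higher <- tab$eq_higher == "TRUE"
  if (!is.null(enzyme)) tab <- tab[tab$enzyme == enzyme, , drop = FALSE]
  if (!is.null(row_class)) {
    tab <- tab[tab$row_class == row_class, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Load the packaged scaffold protein records (with domains attached)
#'
#' @return Named list of [protein_record()]s for `Q9P2N4-3` (ADAMTS9
#'   MDTCS), `P13611-2` (versican V1), `P13611-3` (versican V2) and
#'   `P21810` (biglycan). Sequences are synthetic scaffolds (see module
#'   header).
#' @export
fixture_proteins <- function() {
  recs <- read_fasta(fixture_path("proteins_scaffold_synthetic.fasta"))
  dom <- fixture_domains()
  for (id in names(recs)) {
    d <- dom[dom$protein_id == id, c("name", "start", "end"), drop = FALSE]
    recs[[id]]$domains <- validate_domains(d, protein_length(recs[[id]]),
                                           id)
  }
  recs
}

#' Load the packaged domain interval table
#' @return Data.frame `protein_id`, `name`, `start`, `end`.
#' @export
fixture_domains <- function() {
  read_domain_table(fixture_path("domains_synthetic.tsv"))
}

#' Load the packaged versican V1/V2 position correspondence map
#' @return Data.frame usable with [map_isoform_position()].
#' @export
fixture_isoform_map <- function() {
  read_isoform_map(fixture_path("isoform_map_versican.tsv"))
}

#' Build a site catalog from a packaged evidence table
#'
#' The classify-dedupe-catalog path: classifies each evidence peptide
#' against its working-protease rule, infers candidate sites from the
#' semi-specific rows, merges peptides supporting the same scissile bond,
#' and annotates domains. Spanning rows classify as fully specific and
#' contribute no sites.
#'
#' @param source Fixture label, see [load_fixture()].
#' @param enzyme Optional enzyme subset.
#' @return A `site_catalog` (one row per unique site and enzyme).
#' @export
fixture_site_catalog <- function(source, enzyme = NULL) {
  tab <- load_fixture(source, enzyme = enzyme)
  proteins <- fixture_proteins()
  classified <- do.call(rbind, lapply(
    split(tab, tab$working_protease), function(block) {
      classify_peptides(block, protease_rule(block$working_protease[1L]))
    }))
  catalogs <- lapply(split(classified, classified$enzyme), function(block) {
    calls_from_semi(block, enzyme = block$enzyme[1L], proteins = proteins)
  })
  out <- deduplicate(do.call(rbind, catalogs))
  annotate_domains(out, fixture_domains())
}
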