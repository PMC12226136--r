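# Independent brute-force oracles used to cross-check the implementation,
# plus small constructors for test proteins.

# character-scan oracle for theoretical cleavage positions
oracle_sites <- function(sequence, p1, blocked) {
  chars <- strsplit(sequence, "")[[1]]
  hits <- integer(0)
  for (i in seq_len(length(chars) - 1L)) {
    if (chars[i] %in% p1 && !(chars[i + 1L] %in% blocked)) {
      hits <- c(hits, i)
    }
  }
  hits
}

# per-residue boolean-mask oracle for coverage
oracle_coverage <- function(starts, ends, L) {
  mask <- logical(L)
  for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
  sum(mask) / L
}

# order-statistic linear-interpolation quantile oracle (type 7 convention:
# the q-th quantile sits at rank 1 + (n - 1) q, interpolated linearly)
oracle_quantile7 <- function(x, q) {
  x <- sort(x)
  h <- 1 + (length(x) - 1) * q
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

random_seq <- function(n, letters = c("A", "C", "D", "E", "G", "K", "L",
                                      "P", "R", "S", "T", "V", "Y")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

tiny_protein <- function(sequence, id = "TP1") protein_record(id, sequence)

# peptide observation row for hand-built test cases
obs_row <- function(pep, prev, nxt, start, wp = "trypsin", E = NA, EQ = NA,
                    protein_id = "TP1", mods = "") {
  data.frame(protein_id = protein_id, peptide = pep, prev_aa = prev,
             next_aa = nxt, start = start, end = start + nchar(pep) - 1L,
             working_protease = wp, modifications = mods,
             abundance_E = E, abundance_EQ = EQ, stringsAsFactors = FALSE)
}
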