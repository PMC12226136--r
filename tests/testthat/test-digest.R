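test_that("theoretical sites follow the cleavage rule and proline block", {
  expect_equal(theoretical_sites(tiny_protein("AAKAAKAA"),
                                 protease_rule("trypsin")),
               c(3L, 6L))
  p <- tiny_protein("AKPA")
  expect_equal(theoretical_sites(p, protease_rule("trypsin")), integer(0))
  expect_equal(theoretical_sites(
    p, protease_rule("trypsin", blocked_p1prime = character(0))), 2L)
  # a C-terminal rule residue is never a site (no bond follows it)
  expect_equal(theoretical_sites(tiny_protein("AAK"),
                                 protease_rule("trypsin")), integer(0))
})

test_that("theoretical sites match a character-scan oracle", {
  set.seed(101)
  for (rep in 1:5) {
    p <- tiny_protein(random_seq(200))
    rule <- protease_rule("gluc")
    expect_equal(theoretical_sites(p, rule),
                 oracle_sites(p$sequence, rule$p1_residues,
                              rule$blocked_p1prime))
    rule <- protease_rule("trypsin")
    expect_equal(theoretical_sites(p, rule),
                 oracle_sites(p$sequence, rule$p1_residues,
                              rule$blocked_p1prime))
  }
})

test_that("in-silico digestion enumerates missed cleavages and tiles", {
  p <- tiny_protein("MKTAYR")
  rule <- protease_rule("trypsin")
  d0 <- digest_protein(p, rule, max_missed = 0L, length_range = c(1L, 75L))
  expect_setequal(d0$peptide, c("MK", "TAYR"))
  d1 <- digest_protein(p, rule, max_missed = 1L, length_range = c(1L, 75L))
  expect_setequal(d1$peptide, c("MK", "TAYR", "MKTAYR"))
  expect_equal(d0$prev_aa, c("-", "K"))
  expect_equal(d0$next_aa, c("T", "-"))

  set.seed(202)
  p <- tiny_protein(random_seq(500))
  for (rule in list(protease_rule("trypsin"), protease_rule("gluc"))) {
    d <- digest_protein(p, rule, max_missed = 0L,
                        length_range = c(1L, 10000L))
    d <- d[order(d$start), ]
    expect_equal(paste(d$peptide, collapse = ""), p$sequence)
    expect_equal(d$start[-1], d$end[-nrow(d)] + 1L)  # exact tiling
  }
})

test_that("every digest product classifies as fully specific", {
  set.seed(303)
  p <- tiny_protein(random_seq(400))
  for (name in c("trypsin", "gluc")) {
    rule <- protease_rule(name)
    d <- digest_protein(p, rule, max_missed = 2L, length_range = c(1, 75))
    cl <- classify_peptides(d, rule)
    expect_true(all(cl$peptide_class == "fully"))
    expect_true(all(is.na(cl$p1_pos)))
  }
})

test_that("published semi peptides classify to their printed P1-P1'", {
  rule <- protease_rule("trypsin")
  # autolysis evidence: [E].YSGSETAVER.[I] at 829-838 -> E828-Y829
  cl <- classify_peptides(obs_row("YSGSETAVER", "E", "I", 829), rule)
  expect_equal(cl$peptide_class, "semi_n")
  expect_equal(cl$p1_pos, 828L)
  expect_equal(cl$p1prime_pos, 829L)
  # biglycan evidence: [K].GLQHLYAL.[V] at 112-119 -> L119-V120
  cl <- classify_peptides(obs_row("GLQHLYAL", "K", "V", 112), rule)
  expect_equal(cl$peptide_class, "semi_c")
  expect_equal(cl$p1_pos, 119L)
  expect_equal(cl$p1prime_pos, 120L)
  # conforming at both ends: no site
  cl <- classify_peptides(obs_row("TAVLR", "K", "A", 50), rule)
  expect_equal(cl$peptide_class, "fully")
  expect_true(is.na(cl$p1_pos))
  # protein N-terminus counts as specific; nonconforming C-term -> semi_c
  cl <- classify_peptides(obs_row("MTTA", "-", "V", 1), rule)
  expect_equal(cl$n_term_status, "protein_terminus")
  expect_equal(cl$peptide_class, "semi_c")
})

test_that("classification yields exactly one class per peptide", {
  set.seed(404)
  p <- tiny_protein(random_seq(300))
  rule <- protease_rule("trypsin")
  d <- digest_protein(p, rule, max_missed = 1L, length_range = c(4, 75))
  # truncate half of the peptides on a random side to create semi cases
  for (i in seq_len(nrow(d))) {
    if (i %% 2 == 0 && nchar(d$peptide[i]) > 4) {
      if (i %% 4 == 0) {
        d$start[i] <- d$start[i] + 2L
      } else {
        d$end[i] <- d$end[i] - 2L
      }
      d$peptide[i] <- substr(p$sequence, d$start[i], d$end[i])
      d$prev_aa[i] <- if (d$start[i] == 1) "-" else
        substr(p$sequence, d$start[i] - 1, d$start[i] - 1)
      d$next_aa[i] <- if (d$end[i] == protein_length(p)) "-" else
        substr(p$sequence, d$end[i] + 1, d$end[i] + 1)
    }
  }
  cl <- classify_peptides(d, rule)
  expect_true(all(cl$peptide_class %in%
                    c("fully", "semi_n", "semi_c", "nonspecific")))
  # site present iff semi
  expect_equal(!is.na(cl$p1_pos),
               cl$peptide_class %in% c("semi_n", "semi_c"))
})

test_that("reversing a sequence and swapping flanks maps semi_n to semi_c", {
  # Reversing residue order turns a protease that cleaves C-terminally to
  # its P1 residues into one that cleaves N-terminally to them. The
  # mirrored observation, classified under that mirrored rule (independent
  # oracle below), must carry the swapped class.
  mirror_class <- function(obs, set, blocked) {
    first <- substr(obs$peptide, 1, 1)
    last <- substr(obs$peptide, nchar(obs$peptide), nchar(obs$peptide))
    n_ok <- obs$prev_aa == "-" ||
      (first %in% set && !(obs$prev_aa %in% blocked))
    c_ok <- obs$next_aa == "-" ||
      (obs$next_aa %in% set && !(last %in% blocked))
    if (n_ok && c_ok) "fully" else if (!n_ok && c_ok) "semi_n"
    else if (n_ok && !c_ok) "semi_c" else "nonspecific"
  }
  set.seed(505)
  revstr <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  rule <- protease_rule("trypsin")
  p <- tiny_protein(random_seq(120))
  L <- protein_length(p)
  prev <- function(s) if (s == 1) "-" else substr(p$sequence, s - 1, s - 1)
  nxt <- function(e) if (e == L) "-" else substr(p$sequence, e + 1, e + 1)
  swap <- c(fully = "fully", semi_n = "semi_c", semi_c = "semi_n",
            nonspecific = "nonspecific")
  for (rep in 1:25) {
    s <- sample(2:(L - 10), 1); e <- s + sample(3:8, 1)
    fwd <- obs_row(substr(p$sequence, s, e), prev(s), nxt(e), s)
    bwd <- obs_row(revstr(fwd$peptide), fwd$next_aa, fwd$prev_aa,
                   L - e + 1L)
    a <- classify_peptides(fwd, rule)$peptide_class
    b <- mirror_class(bwd, rule$p1_residues, rule$blocked_p1prime)
    expect_equal(b, unname(swap[a]))
  }
})

test_that("coverage equals the per-residue mask oracle", {
  p <- tiny_protein(random_seq(100))
  expect_equal(coverage(obs_row(substr(p$sequence, 1, 10), "-", "A", 1), p),
               0.10)
  two <- rbind(obs_row(substr(p$sequence, 1, 10), "-", "A", 1),
               obs_row(substr(p$sequence, 5, 20), "A", "A", 5))
  expect_equal(coverage(two, p), 0.20)

  set.seed(606)
  p <- tiny_protein(random_seq(300))
  starts <- sample(1:290, 50, replace = TRUE)
  ends <- pmin(starts + sample(4:30, 50, replace = TRUE), 300L)
  peps <- do.call(rbind, lapply(1:50, function(i)
    obs_row(substr(p$sequence, starts[i], ends[i]), "A", "A", starts[i])))
  expect_equal(coverage(peps, p), oracle_coverage(starts, ends, 300L))
})

test_that("site density reports gaps and residue scarcity", {
  p <- tiny_protein("AAKAAKAA")
  rep1 <- site_density(p, protease_rule("trypsin"))
  expect_equal(rep1$n_sites, 2L)
  expect_equal(rep1$gaps, 3L)
  expect_equal(rep1$mean_gap, 3)
  expect_equal(rep1$max_gap, 3)
  expect_equal(unname(rep1$residue_counts["K"]), 2L)

  # region with no sites: gaps default to the region length
  rep0 <- site_density(p, protease_rule("gluc"))
  expect_equal(rep0$n_sites, 0L)
  expect_equal(rep0$mean_gap, 8)
  expect_equal(rep0$max_gap, 8)

  set.seed(707)
  p <- tiny_protein(random_seq(400))
  rule <- protease_rule("gluc")
  rep <- site_density(p, rule, region = c(50L, 350L),
                      residues = c("D", "E"))
  osites <- oracle_sites(p$sequence, rule$p1_residues,
                         rule$blocked_p1prime)
  osites <- osites[osites >= 50 & osites <= 350]
  expect_equal(rep$sites, osites)
  expect_equal(rep$max_gap, max(diff(osites)))
  chars <- strsplit(substr(p$sequence, 50, 350), "")[[1]]
  expect_equal(unname(rep$residue_counts),
               c(sum(chars == "D"), sum(chars == "E")))
})
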