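# Site catalog bookkeeping: deduplication, domain annotation, cross-enzyme
# sharing, union/novelty, isoform mapping.

empty_calls_for_test <- function() fixture_site_catalog("Table2")[0, ]

test_that("deduplication pools evidence and is idempotent", {
  t4 <- fixture_site_catalog("Table4", enzyme = "ADAMTS1")
  expect_equal(nrow(t4), 12L)
  expect_equal(nrow(deduplicate(t4)), 12L)
  expect_equal(deduplicate(deduplicate(t4))$n_semi_peptides,
               deduplicate(t4)$n_semi_peptides)
  expect_equal(nrow(deduplicate(empty_calls_for_test())), 0L)

  # n random distinct sites stay n entries
  set.seed(8)
  pos <- sample(1000, 37)
  calls <- do.call(rbind, lapply(pos, function(p) {
    k <- fixture_site_catalog("Table2")[1, ]
    k$p1_pos <- p; k$p1prime_pos <- p + 1L
    k
  }))
  expect_equal(nrow(deduplicate(calls)), 37L)
})

test_that("domain annotation reproduces the published domain labels", {
  for (src in c("Table1", "Table2", "Table3", "Table4", "Table5")) {
    tab <- load_fixture(src, row_class = "semi")
    cat_by_enzyme <- lapply(unique(tab$enzyme), function(e)
      fixture_site_catalog(src, enzyme = e))
    combined <- do.call(rbind, cat_by_enzyme)
    for (i in seq_len(nrow(tab))) {
      hit <- combined[combined$p1_pos == tab$paper_p1_pos[i] &
                        combined$enzyme == tab$enzyme[i] &
                        combined$protein_id == tab$protein_id[i], ]
      expect_equal(hit$domain, tab$paper_domain[i],
                   info = paste(src, tab$paper_site[i]))
    }
  }
})

test_that("positions outside every domain interval are interdomain", {
  dom <- data.frame(protein_id = "P", name = c("D1", "D2"),
                    start = c(10L, 40L), end = c(20L, 60L))
  calls <- fixture_site_catalog("Table2")[1:2, ]
  calls$protein_id <- "P"
  calls$p1_pos <- c(15L, 30L)
  ann <- annotate_domains(calls, dom)
  expect_equal(ann$domain, c("D1", "interdomain"))
  # nested intervals resolve to the first in table order
  dom2 <- rbind(dom, data.frame(protein_id = "P", name = "D1a",
                                start = 12L, end = 16L))
  expect_equal(annotate_domains(calls, dom2)$domain[1], "D1")
})

test_that("cross-enzyme sharing reproduces the published shared sites", {
  v2 <- deduplicate(rbind(fixture_site_catalog("Table3"),
                          fixture_site_catalog("Table4")))
  rep <- compare_enzymes(v2)
  expect_setequal(shared_between(rep, "ADAMTS5", "ADAMTS9"),
                  c(1433L, 1451L))
  expect_setequal(shared_between(rep, "ADAMTS1", "ADAMTS9"), 26L)
  expect_setequal(shared_between(rep, "ADAMTS1", "ADAMTS5"),
                  c(823L, 1538L))
  expect_equal(rep$union_size, 42L)

  bg <- fixture_site_catalog("Table5")
  rep5 <- compare_enzymes(bg)
  expect_equal(rep5$shared, 160L)
  expect_setequal(shared_between(rep5, "ADAMTS1", "ADAMTS9"), 160L)
  expect_equal(rep5$union_size, 27L)
  # union = sum of exclusives + shared positions
  expect_equal(rep5$union_size,
               sum(rep5$exclusive) + length(rep5$shared))

  # single catalog: nothing can be shared; order symmetry
  single <- compare_enzymes(fixture_site_catalog("Table4", "ADAMTS4"))
  expect_length(single$shared, 0L)
  rep_swapped <- compare_enzymes(deduplicate(rbind(
    fixture_site_catalog("Table4"), fixture_site_catalog("Table3"))))
  expect_equal(rep_swapped$positions, rep$positions)
})

test_that("union counts are monotone and novelty subtracts known sites", {
  t3 <- fixture_site_catalog("Table3")
  t4 <- fixture_site_catalog("Table4")
  u1 <- union_novel(t3)
  u2 <- union_novel(list(t3, t4))
  expect_equal(u1$union_size, 21L)
  expect_equal(u2$union_size, 42L)
  expect_gte(u2$union_size, u1$union_size)

  u5 <- union_novel(fixture_site_catalog("Table5"))
  expect_equal(u5$union_size, 27L)

  known <- u2$union_positions
  expect_equal(union_novel(list(t3, t4), known)$n_novel, 0L)
  known_half <- known[1:10, ]
  expect_equal(union_novel(list(t3, t4), known_half)$n_novel, 32L)
})

test_that("isoform positions map through the packaged correspondence", {
  map <- fixture_isoform_map()
  # G3 cleavage correspondence between versican V2 and V1 numbering
  expect_equal(map_isoform_position(1450, map, "P13611-3", "P13611-2"),
               2217L)
  expect_equal(map_isoform_position(1451, map, "P13611-3", "P13611-2"),
               2218L)
  # reverse direction and identity
  expect_equal(map_isoform_position(2218, map, "P13611-2", "P13611-3"),
               1451L)
  expect_equal(map_isoform_position(1451, map, "P13611-3", "P13611-3"),
               1451L)
  # shared G1 block maps with zero offset
  expect_equal(map_isoform_position(26, map, "P13611-3", "P13611-2"), 26L)
  expect_error(map_isoform_position(900, map, "P13611-3", "P13611-2"),
               "not covered")
})
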