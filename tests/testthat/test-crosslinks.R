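test_that("cross-link CSV loading validates, collapses and rejects", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Protein1,Residue1,Protein2,Residue2,Linker",
               "Mis18a,77,Mis18b,120,EDC",
               "Mis18a,150,Mis18b,40,SDA",
               "Mis18b,10,Mis18bp1,30,EDC",
               "Mis18a,5,Mis18bp1,99,EDC"), p)
  links <- load_crosslinks(p)
  expect_equal(nrow(links), 4L)
  expect_equal(attr(links, "n_duplicates"), 0L)

  # duplicated unordered pair collapses with a count
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Protein1,Residue1,Protein2,Residue2,Linker",
               "A,1,B,2,EDC",
               "B,2,A,1,EDC",
               "A,1,B,2,SDA"), p2)
  expect_message(l2 <- load_crosslinks(p2), "collapsed 1 duplicate")
  expect_equal(nrow(l2), 2L)

  # self-link dropped with a warning
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Protein1,Residue1,Protein2,Residue2,Linker",
               "A,77,A,77,EDC", "A,1,B,2,EDC"), p3)
  expect_warning(l3 <- load_crosslinks(p3), "self-link")
  expect_equal(nrow(l3), 1L)

  # schema errors name the problem
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Protein1,Residue1,Protein2,Linker", "A,1,B,EDC"), p4)
  expect_error(load_crosslinks(p4), "Residue2")
  p5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Protein1,Residue1,Protein2,Residue2,Linker", "A,x,B,2,EDC"), p5)
  expect_error(load_crosslinks(p5), "row")
})

test_that("chain maps round-trip through JSON and are validated", {
  cm <- list(Mis18a = c("A", "C"), Mis18b = "B")
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cm, p)
  expect_equal(read_chain_map(p), cm)
  s <- mk_ca_structure(diag(3), chain = "A")
  expect_error(score_crosslinks(s, crosslink_table("X", 1, "Y", 2),
                                list(X = "A", Y = "Q")),
               "absent from the structure")
})

test_that("link_distance takes the minimum over copies and flags unmappable", {
  # single copies at a known distance
  s <- combine_structures(list(
    mk_ca_structure(matrix(c(0, 0, 0), 1, 3), chain = "A"),
    mk_ca_structure(matrix(c(0, 0, 10), 1, 3), chain = "B")))
  lk <- crosslink_table("pa", 1, "pb", 1)
  got <- link_distance(s, lk[1, ], list(pa = "A", pb = "B"))
  expect_equal(got$distance, 10)

  # two copies of pa: min over copy pairs decides (30 vs 12)
  s2 <- combine_structures(list(
    mk_ca_structure(matrix(c(0, 0, 30), 1, 3), chain = "A"),
    mk_ca_structure(matrix(c(0, 0, 12), 1, 3), chain = "C"),
    mk_ca_structure(matrix(c(0, 0, 0), 1, 3), chain = "B")))
  got2 <- link_distance(s2, lk[1, ], list(pa = c("A", "C"), pb = "B"))
  expect_equal(got2$distance, 12)
  expect_equal(got2$chain_a, "C")

  # residue with no CA anywhere -> unmappable (NULL)
  lk2 <- crosslink_table("pa", 99, "pb", 1)
  expect_null(link_distance(s2, lk2[1, ], list(pa = c("A", "C"), pb = "B")))
  expect_error(link_distance(s2, lk[1, ], list(pb = "B")), "absent")
})

test_that("satisfaction uses a strict threshold and excludes unmappable links", {
  s <- combine_structures(list(
    mk_ca_structure(matrix(c(0, 0, 0, 0, 0, 0), 2, 3, byrow = TRUE),
                    resno = 1:2, chain = "A"),
    mk_ca_structure(matrix(c(0, 0, 21.99, 0, 0, 22.00), 2, 3, byrow = TRUE),
                    resno = 1:2, chain = "B")))
  cm <- list(pa = "A", pb = "B")
  links <- crosslink_table("pa", c(1, 2), "pb", c(1, 2))
  rep <- score_crosslinks(s, links, cm, threshold = 22)
  expect_true(rep$per_link$satisfied[1])    # 21.99 < 22
  expect_false(rep$per_link$satisfied[2])   # 22.00 is violated
  expect_equal(rep$fraction_satisfied, 0.5)

  # unmappable link excluded from the denominator
  links3 <- crosslink_table("pa", c(1, 2, 1), "pb", c(1, 2, 50))
  rep3 <- score_crosslinks(s, links3, cm)
  expect_equal(rep3$n_links, 3L)
  expect_equal(rep3$n_mappable, 2L)
  expect_equal(rep3$fraction_satisfied, 0.5)
  expect_error(score_crosslinks(s, crosslink_table("pa", 50, "pb", 60), cm),
               "no mappable")
})

test_that("scoring matches an independent brute force on seeded fixtures", {
  set.seed(101)
  for (rep_i in 1:50) {
    s <- combine_structures(list(
      mk_blob(15, centre = c(0, 0, 0), chain = "A"),
      mk_blob(15, centre = c(15, 0, 0), chain = "B"),
      mk_blob(15, centre = c(0, 18, 0), chain = "C")))
    cm <- list(p1 = c("A", "C"), p2 = "B")   # p1 has two copies
    pa <- sample(c("p1", "p2"), 6, TRUE)
    ra <- sample(15, 6, TRUE); rb <- sample(15, 6, TRUE)
    ok <- !(pa == "p2" & ra == rb)
    if (!any(ok)) next
    links <- crosslink_table(pa[ok], ra[ok], "p2", rb[ok])
    got <- score_crosslinks(s, links, cm)
    want <- brute_score(s, links, cm)
    expect_equal(got$fraction_satisfied, want$fraction)
    expect_equal(got$n_mappable, want$n_mappable)
    expect_equal(got$per_link$min_distance, want$distances, tolerance = 1e-9)
  }
})

test_that("satisfaction is monotone in threshold and rigid-invariant", {
  set.seed(55)
  s <- combine_structures(list(mk_blob(20, chain = "A"),
                               mk_blob(20, centre = c(12, 0, 0), chain = "B")))
  cm <- list(pa = "A", pb = "B")
  links <- crosslink_table("pa", sample(20, 8, TRUE), "pb", sample(20, 8, TRUE))
  fr <- vapply(c(5, 10, 15, 22, 30, 50),
               function(th) score_crosslinks(s, links, cm, th)$fraction_satisfied,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
  base <- score_crosslinks(s, links, cm)
  for (i in 1:5) {
    tr <- random_transform()
    moved <- apply_transform(s, tr)
    got <- score_crosslinks(moved, links, cm)
    expect_equal(got$per_link$min_distance, base$per_link$min_distance,
                 tolerance = 1e-9)
  }
})

test_that("satisfaction comparison tabulates complementary percentages", {
  s <- combine_structures(list(
    mk_ca_structure(matrix(0, 1, 3), chain = "A"),
    mk_ca_structure(matrix(c(0, 0, 10), 1, 3), chain = "B")))
  cm <- list(pa = "A", pb = "B")
  good <- score_crosslinks(s, crosslink_table("pa", 1, "pb", 1), cm)
  s2 <- apply_transform(s, rigid_transform())
  s2$atoms$z[2] <- 40
  bothlk <- crosslink_table("pa", c(1, 1), "pb", c(1, 1), linker = c("EDC", "SDA"))
  half <- score_crosslinks(s2, crosslink_table("pa", 1, "pb", 1), cm)
  tab <- satisfaction_comparison(list(good = good, bad = half))
  expect_equal(tab$pct_satisfied, c(100, 0))
  expect_equal(tab$pct_violated, c(0, 100))
  expect_equal(tab$pct_satisfied + tab$pct_violated, c(100, 100))
  csv <- withr::local_tempfile(fileext = ".csv")
  satisfaction_comparison(list(m = good), csv = csv)
  expect_true(file.exists(csv))
})
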