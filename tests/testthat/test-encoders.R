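test_that("one-hot pair map has the documented geometry", {
  m <- encode_onehot_pair("NLVPMVATV", "CASSQWSNEKLFF")
  expect_equal(dim(unclass(m)), c(32L, 20L))
  expect_equal(sum(m), 9 + 13)                 # one 1 per residue
  expect_equal(sum(rowSums(unclass(m)) == 0), 32 - 22)  # padding rows
  expect_equal(attr(m, "kind"), "onehot")

  # full-length pair leaves no padding
  full <- encode_onehot_pair(strrep("A", 11), paste0("C", strrep("S", 20)))
  expect_true(all(rowSums(unclass(full)) == 1))

  expect_error(encode_onehot_pair("AHRTAHR", "CASSQWSNEKLFF"), "length")
  expect_error(encode_onehot_pair("NLVPMVATV", "CASS"), "length")
})

test_that("one-hot rows index residues and columns count them", {
  set.seed(4)
  for (i in 1:10) {
    pep <- random_pep(1, len = sample(8:11, 1))
    cdr <- paste0("C", random_pep(1, len = sample(7:20, 1)))
    m <- unclass(encode_onehot_pair(pep, cdr))
    expect_true(all(rowSums(m) %in% c(0, 1)))
    combined <- c(strsplit(pep, "")[[1]], strsplit(cdr, "")[[1]])
    expect_equal(colSums(m), table(factor(combined, levels = AA_ALPHABET))[AA_ALPHABET],
                 ignore_attr = TRUE)
    # peptide occupies rows 1..len, CDR3 rows 12..(11+len)
    expect_equal(AA_ALPHABET[apply(m[seq_len(nchar(pep)), ], 1, which.max)],
                 strsplit(pep, "")[[1]])
    expect_equal(AA_ALPHABET[apply(m[11 + seq_len(nchar(cdr)), ], 1, which.max)],
                 strsplit(cdr, "")[[1]])
  }
})

test_that("phychem table standardizes each scale to mean 0, variance 1", {
  tab <- load_phychem_table()
  expect_equal(ncol(tab$std), 21L)
  expect_equal(unname(colMeans(tab$std)), rep(0, 21), tolerance = 1e-12)
  expect_equal(unname(colMeans(tab$std^2)), rep(1, 21), tolerance = 1e-12)

  m <- encode_phychem_pair("NLVPMVATV", "CASSQWSNEKLFF", tab)
  expect_equal(dim(unclass(m)), c(32L, 21L))
  expect_equal(unname(m[1, ]), unname(tab$std["N", ]))  # row = residue lookup
  # identical residues at different positions share a row
  expect_equal(unname(m[14, ]), unname(m[15, ]))  # S at CDR3 pos 3 and 4
  expect_equal(unname(m[13, ]), unname(m[7, ]))   # A in CDR3 and in peptide
})

test_that("phychem padding rows are zero and rows are position-independent", {
  tab <- load_phychem_table()
  m <- unclass(encode_phychem_pair("NLVPMVATV", "CASSQWSNEKLFF", tab))
  expect_true(all(m[10:11, ] == 0))   # peptide padding
  expect_true(all(m[25:32, ] == 0))   # CDR3 padding
  m2 <- unclass(encode_phychem_pair("AAAAAAAA", "CAAAAAAAAAAAAAAA", tab))
  expect_equal(m2[1, ], m2[8, ])      # same residue, same row values
})

test_that("compute_aac returns normalized residue frequencies", {
  expect_equal(unname(compute_aac("AAAA")["A"]), 1)
  aac <- compute_aac("CASS")
  expect_equal(unname(aac[c("C", "A", "S")]), c(0.25, 0.25, 0.5))
  expect_equal(sum(aac), 1)
  set.seed(2)
  for (s in random_pep(5, len = 15)) expect_equal(sum(compute_aac(s)), 1)
  expect_error(compute_aac(""), "empty")
  expect_error(compute_aac("ABX"), "alphabet")
})

test_that("AAPP matrices implement count_{x,i} / N_t over positions 2-21", {
  recs <- pair_df("NLVPMVATV", c("CASSLGQF", "CASSPGQF"))
  tab <- build_aapp_table(recs)
  m <- tab$maps[["NLVPMVATV"]]
  expect_equal(dim(m), c(20L, 20L))
  expect_equal(m["pos2", "A"], 1)         # both CDR3s have A at position 2
  expect_equal(m["pos5", "L"], 0.5)
  expect_equal(m["pos5", "P"], 0.5)
  expect_true(all(m["pos9", ] == 0))      # both CDR3s end at position 8
  expect_equal(tab$tcr_counts[["NLVPMVATV"]], 2L)
  expect_error(build_aapp_table(pair_df("NLVPMVATV", "CASSLGQF", label = 0L)),
               "positive")
})

test_that("AAPP column-sum law holds on generated tables", {
  ds <- tiny_dataset(seed = 23)
  pos <- ds[ds$label == 1, ]
  tab <- build_aapp_table(pos)
  for (p in names(tab$maps)) {
    cdr3s <- pos$cdr3[pos$peptide == p]
    nt <- length(cdr3s)
    for (x in c(2L, 5L, 12L, 17L, 21L)) {
      expect_equal(sum(tab$maps[[p]][x - 1L, ]),
                   sum(nchar(cdr3s) >= x) / nt)
    }
    expect_equal(sum(tab$maps[[p]]["pos2", ]), 1)
  }
  # repertoire of size 1 gives a 0/1 matrix
  solo <- build_aapp_table(pair_df("GILGFVFTL", "CASSIRSSYEQYF"))
  expect_true(all(solo$maps[[1]] %in% c(0, 1)))
})

test_that("lookup_aapp returns own map or the MED neighbor's", {
  ds <- tiny_dataset(seed = 29)
  tab <- build_aapp_table(ds[ds$label == 1, ])
  p1 <- names(tab$maps)[1]
  own <- lookup_aapp(p1, tab)
  expect_equal(unclass(unname(own)), unname(tab$maps[[p1]]), ignore_attr = TRUE)
  expect_equal(length(own), 400L)
  expect_equal(attr(own, "distance"), 0L)

  # unseen peptide one substitution away from exactly one training peptide
  q <- perturb_peptides(p1, n_edits = 1L, seed = 3)
  d_all <- vapply(names(tab$maps), function(cc) edit_distance(q, cc), integer(1))
  stopifnot(sum(d_all == min(d_all)) == 1L)  # fixture assumption
  got <- lookup_aapp(q, tab)
  expect_equal(attr(got, "source_peptide"), names(which.min(d_all)))
  expect_equal(unname(unclass(got)), unname(tab$maps[[which.min(d_all)]]),
               ignore_attr = TRUE)

  # brute-force argmin equivalence with lexicographic ties
  for (q2 in random_pep(8, len = 9, seed = 41)) {
    got2 <- lookup_aapp(q2, tab)
    d <- vapply(names(tab$maps), function(cc) edit_distance(q2, cc), integer(1))
    best <- sort(names(d)[d == min(d)])[1]
    expect_equal(attr(got2, "source_peptide"), best)
  }
  empty_tab <- build_aapp_table(pair_df("NLVPMVATV", "CASSLGQF")[0, ])
  expect_error(lookup_aapp("NLVPMVATV", empty_tab), "empty")
})

test_that("fuse_pair assembles the four schemes with the right shapes", {
  ds <- tiny_dataset(seed = 37)
  tab <- build_aapp_table(ds[ds$label == 1, ])
  phychem <- load_phychem_table()
  pep <- ds$peptide[1]; cdr <- ds$cdr3[1]
  tables <- list(aapp = tab, phychem = phychem)

  fo_aapp <- fuse_pair(pep, cdr, "onehot-aapp", tables)
  expect_equal(dim(unclass(fo_aapp$module1)), c(32L, 20L))
  expect_equal(dim(unclass(fo_aapp$module2)), c(20L, 20L))
  expect_equal(length(fo_aapp$module1), 640L)
  expect_equal(length(fo_aapp$module2), 400L)

  fo_aac <- fuse_pair(pep, cdr, "onehot-aac", tables)
  expect_equal(dim(unclass(fo_aac$module2)), c(2L, 20L))
  expect_equal(unname(unclass(fo_aac$module2)[1, ]), unname(compute_aac(pep)))
  expect_equal(unname(unclass(fo_aac$module2)[2, ]), unname(compute_aac(cdr)))

  fp_aapp <- fuse_pair(pep, cdr, "phychem-aapp", tables)
  expect_equal(dim(unclass(fp_aapp$module1)), c(32L, 21L))

  # purity: identical calls give identical outputs
  expect_identical(fuse_pair(pep, cdr, "onehot-aapp", tables),
                   fuse_pair(pep, cdr, "onehot-aapp", tables))

  expect_error(fuse_pair(pep, cdr, "onehot-blosum", tables), "unknown")
  expect_error(fuse_pair(pep, cdr, "phychem-aac", list()), "phychem")
  expect_error(fuse_pair(pep, cdr, "onehot-aapp", list()), "aapp")
})

test_that("AAPP serialization round-trips exactly", {
  ds <- tiny_dataset(seed = 43)
  tab <- build_aapp_table(ds[ds$label == 1, ])
  f <- tempfile(fileext = ".csv")
  write_aapp_table(tab, f)
  back <- read_aapp_table(f)
  expect_identical(back$tcr_counts[names(tab$tcr_counts)], tab$tcr_counts)
  for (p in names(tab$maps)) {
    expect_identical(back$maps[[p]], tab$maps[[p]])
    expect_identical(back$counts[[p]], tab$counts[[p]])
  }
})
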