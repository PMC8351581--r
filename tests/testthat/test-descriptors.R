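test_that("tripeptide composition matches hand-enumerated cases", {
  v <- compute_tpc("AAA")
  expect_length(v, 8000L)
  expect_equal(unname(v[["TPC:AAA"]]), 1.0)
  expect_equal(sum(v), 1.0)

  v <- compute_tpc("ACDA")   # two overlapping windows: ACD, CDA
  expect_equal(unname(v[["TPC:ACD"]]), 0.5)
  expect_equal(unname(v[["TPC:CDA"]]), 0.5)
  expect_equal(sum(v != 0), 2L)

  expect_error(compute_tpc("AC"), "at least 3")
})

test_that("descriptor dispatch is consistent and examples check out", {
  expect_identical(compute_descriptor("ACDA", descriptor_spec("TPC")),
                   compute_tpc("ACDA"))

  d <- compute_descriptor("AAA", descriptor_spec("CKSAAP", k_max = 0))
  expect_equal(unname(d[["CKSAAP:AA.gap0"]]), 1.0)  # 2 gap-0 AA pairs / 2
  expect_equal(sum(d != 0), 1L)

  d <- compute_descriptor("AAAAA", descriptor_spec("CTDC"))
  # A's group has share 1 under every property, all other groups 0
  expect_equal(sum(d == 1), 7L)
  expect_equal(sum(d == 0), 14L)
})

test_that("output dimensionality follows the closed forms for all classes", {
  set.seed(21)
  s <- random_sequence(80)
  cases <- list(
    list(spec = descriptor_spec("TPC"), dim = 8000L),
    list(spec = descriptor_spec("GTPC"), dim = 125L),
    list(spec = descriptor_spec("CKSAAP"), dim = 2400L),
    list(spec = descriptor_spec("CKSAAP", k_max = 2), dim = 1200L),
    list(spec = descriptor_spec("CKSAAGP"), dim = 150L),
    list(spec = descriptor_spec("KSCTriad"), dim = 2058L),
    list(spec = descriptor_spec("KSCTriad", k_max = 1), dim = 686L),
    list(spec = descriptor_spec("DDE"), dim = 400L),
    list(spec = descriptor_spec("CTDC"), dim = 21L),
    list(spec = descriptor_spec("CTDT"), dim = 21L),
    list(spec = descriptor_spec("CTDD"), dim = 105L),
    list(spec = descriptor_spec("Moran"), dim = 240L),
    list(spec = descriptor_spec("Geary", nlag = 10), dim = 80L),
    list(spec = descriptor_spec("NMBroto"), dim = 240L),
    list(spec = descriptor_spec("SOCNumber", nlag = 12), dim = 24L),
    list(spec = descriptor_spec("QSOrder"), dim = 100L),
    list(spec = descriptor_spec("PAAC", lambda = 5), dim = 25L),
    list(spec = descriptor_spec("APAAC"), dim = 80L)
  )
  for (case in cases) {
    expect_equal(descriptor_length(case$spec), case$dim,
                 label = case$spec$class_name)
    v <- compute_descriptor(s, case$spec)
    expect_length(v, case$dim)
    expect_true(all(is.finite(v)), label = case$spec$class_name)
    expect_equal(anyDuplicated(names(v)), 0L)
  }
})

test_that("composition-type classes satisfy their normalization identities", {
  set.seed(22)
  for (rep in 1:5) {
    s <- random_sequence(sample(35:300, 1))
    expect_equal(sum(compute_tpc(s)), 1.0)
    expect_equal(sum(compute_descriptor(s, descriptor_spec("GTPC"))), 1.0)
    ctdc <- compute_descriptor(s, descriptor_spec("CTDC"))
    for (p in seq_len(7)) {
      expect_equal(sum(ctdc[(3 * p - 2):(3 * p)]), 1.0)
    }
    ck <- compute_descriptor(s, descriptor_spec("CKSAAP", k_max = 3))
    for (k in 0:3) {
      expect_equal(sum(ck[(400 * k + 1):(400 * k + 400)]), 1.0)
    }
  }
})

test_that("descriptors are deterministic and agree with brute-force on spot checks", {
  set.seed(23)
  s <- random_sequence(60)
  spec <- descriptor_spec("DDE")
  expect_identical(compute_descriptor(s, spec), compute_descriptor(s, spec))
  for (cl in c("TPC", "CTDT", "Moran", "PAAC")) {
    spec <- descriptor_spec(cl, nlag = 8, lambda = 8)
    expect_lt(max(abs(compute_descriptor(s, spec) -
                        oracle_descriptor(s, spec))), 1e-10)
  }
})

test_that("sequences below a class minimum raise informative errors", {
  expect_error(compute_descriptor(random_sequence(20),
                                  descriptor_spec("Moran", nlag = 30)),
               "at least 31")
  expect_error(compute_descriptor(random_sequence(10),
                                  descriptor_spec("PAAC", lambda = 30)),
               "at least 31")
  expect_error(compute_descriptor(random_sequence(5),
                                  descriptor_spec("KSCTriad", k_max = 5)),
               "at least 13")
})

test_that("feature matrices preserve order, match per-record output, and serialize", {
  set.seed(24)
  recs <- random_records(5, len_range = c(40, 80))
  spec <- descriptor_spec("CTDD")
  m <- build_feature_matrix(recs, spec)
  expect_equal(dim(m), c(5L, 105L))
  expect_equal(rownames(m), recs$id)
  for (i in seq_len(5)) {
    expect_equal(unname(m[i, ]),
                 unname(compute_descriptor(recs$sequence[i], spec)))
  }
  # permuting record order permutes rows only
  perm <- c(3, 1, 5, 2, 4)
  rp <- protein_records(recs$id[perm], recs$sequence[perm])
  expect_equal(build_feature_matrix(rp, spec), m[perm, ])

  # aggregated too-short error names every offender
  bad <- protein_records(c("ok1", "tiny1", "tiny2"),
                         c(random_sequence(40), "MK", "ACD"))
  expect_error(build_feature_matrix(bad, descriptor_spec("CKSAAP", k_max = 2)),
               "tiny1, tiny2")

  tf <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(m, tf)
  expect_equal(read_feature_matrix(tf), m)
})
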