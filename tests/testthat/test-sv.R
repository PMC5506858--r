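# Junction linkage, complex-event decomposition and mechanism calls.

chain_junctions <- function(n, chrom = "5", start = 2e7, gap = 5000) {
  # n junctions whose breakends form a head-to-tail chain within gap
  pos <- start + cumsum(rep(gap, 2 * n)) - gap
  make_junctions(chromA = chrom, posA = as.integer(pos[seq(1, 2 * n, 2)]),
                 chromB = chrom, posB = as.integer(pos[seq(2, 2 * n, 2)]),
                 strandA = "+", strandB = "-")
}

test_that("chained junctions form one cluster; four or more is complex", {
  four <- link_junctions(chain_junctions(4))
  expect_equal(length(unique(four$cluster_id)), 1)
  expect_equal(unique(four$complexity), "complex")

  three <- link_junctions(chain_junctions(3))
  expect_equal(length(unique(three$cluster_id)), 1)
  expect_equal(unique(three$complexity), "simple")
})

test_that("distant junction groups stay separate clusters", {
  far <- dplyr::bind_rows(chain_junctions(2, start = 2e7),
                          chain_junctions(2, start = 7e7))
  linked <- link_junctions(far)
  expect_equal(length(unique(linked$cluster_id)), 2)
  expect_error(link_junctions(far, window = -1), "nonnegative")
})

test_that("clustering equals all-pairs transitive closure", {
  closure_oracle <- function(jx, window) {
    n <- nrow(jx)
    adj <- diag(TRUE, n)
    ends <- function(i) {
      list(c(jx$chromA[i], jx$posA[i]), c(jx$chromB[i], jx$posB[i]))
    }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      for (ei in ends(i)) for (ej in ends(j)) {
        if (ei[1] == ej[1] &&
            abs(as.numeric(ei[2]) - as.numeric(ej[2])) <= window) {
          adj[i, j] <- TRUE
        }
      }
    }
    repeat {
      nxt <- (adj %*% adj) > 0
      if (identical(nxt, adj > 0)) break
      adj <- nxt
    }
    # canonical component labels
    match(apply(adj, 1, function(r) paste(which(r), collapse = ",")),
          unique(apply(adj, 1, function(r) {
            paste(which(r), collapse = ",")
          })))
  }
  set.seed(21)
  for (rep in 1:5) {
    n <- 40
    jx <- make_junctions(
      chromA = sample(c("1", "2", "3"), n, replace = TRUE),
      posA = as.integer(sample.int(2e6, n)),
      chromB = sample(c("1", "2", "3"), n, replace = TRUE),
      posB = as.integer(sample.int(2e6, n)),
      strandA = sample(c("+", "-"), n, replace = TRUE),
      strandB = sample(c("+", "-"), n, replace = TRUE))
    linked <- link_junctions(jx, window = 50000)
    oracle <- closure_oracle(jx, 50000)
    impl <- match(linked$cluster_id, unique(linked$cluster_id))
    expect_equal(impl, oracle)
  }
})

test_that("clustering is order-invariant and partitions the input", {
  set.seed(22)
  n <- 30
  jx <- make_junctions(
    chromA = sample(c("1", "2"), n, replace = TRUE),
    posA = as.integer(sample.int(1e6, n)),
    chromB = sample(c("1", "2"), n, replace = TRUE),
    posB = as.integer(sample.int(1e6, n)))
  l1 <- link_junctions(jx, window = 30000)
  perm <- sample(n)
  l2 <- link_junctions(jx[perm, ], window = 30000)
  # same partition: co-membership matrices agree
  co1 <- outer(l1$cluster_id, l1$cluster_id, "==")
  co2p <- outer(l2$cluster_id, l2$cluster_id, "==")
  co2 <- co2p[order(perm), order(perm)]
  expect_equal(co1, co2)
  expect_equal(sum(table(l1$cluster_id)), n)
})

test_that("complex fraction is monotone in the linkage window", {
  set.seed(23)
  n <- 60
  jx <- make_junctions(
    chromA = "4", posA = as.integer(sort(sample.int(5e6, n))),
    chromB = "4", posB = as.integer(sort(sample.int(5e6, n)) + 10L))
  fracs <- vapply(c(1e3, 1e4, 1e5, 1e6), function(w) {
    composition_stats(link_junctions(jx, w))$complex_fraction
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("composition stats report strata and degenerate inputs", {
  tr <- make_junctions(chromA = c("1", "2"), chromB = c("3", "4"),
                       posA = c(1e6L, 2e6L), posB = c(1e6L, 2e6L))
  linked <- link_junctions(tr)
  comp <- composition_stats(linked)
  overall <- comp$by_class[comp$by_class$stratum == "overall", ]
  expect_equal(overall$translocation, 1)
  # empty complex stratum -> NA, not 0
  cx <- comp$by_class[comp$by_class$stratum == "complex", ]
  expect_true(is.na(cx$translocation))

  empty <- composition_stats(
    dplyr::mutate(tr[0, ], complexity = character()))
  expect_true(all(is.na(
    empty$by_class[empty$by_class$stratum == "overall",
                   c("deletion", "translocation")])))
})

test_that("simulated complex/simple assignment is recovered exactly", {
  cfg <- sim_config(n_patients = 15, samples_per_patient = 1,
                    complex_event_rate = 0.8, seed = 29)
  co <- simulate_cohort(cfg)
  linked <- link_junctions(co$junctions)
  truth <- co$truth$junction_truth
  expect_equal(linked$complexity == "complex", truth$complex)
  comp <- composition_stats(linked)
  expect_equal(comp$complex_fraction, mean(truth$complex))
})

test_that("mechanism classification follows the decision table", {
  jx <- make_junctions(
    posA = c(1e6L, 2e6L, 3e6L), posB = c(101e6L, 102e6L, 103e6L),
    homology_len = c(0L, 5L, 0L), insertion_len = c(0L, 0L, 25L))
  expect_equal(classify_mechanism(jx), c("NHEJ", "MMEJ", "MMBIR"))
  # totality and determinism on valid records
  set.seed(30)
  feats <- simulate_junction_features(
    sample(c("MMEJ", "NHEJ", "MMBIR"), 50, replace = TRUE))
  jr <- make_junctions(posA = 1:50 * 1000000L,
                       posB = 1:50 * 1000000L + 500L,
                       homology_len = feats$homology_len,
                       insertion_len = feats$insertion_len)
  m1 <- classify_mechanism(jr)
  expect_true(all(m1 %in% c("MMEJ", "NHEJ", "MMBIR")))
  expect_identical(m1, classify_mechanism(jr))
  # malformed features
  bad <- jx; bad$homology_len[1] <- NA_integer_
  expect_equal(classify_mechanism(bad)[1], "unclassified")
})

test_that("mechanism profile recovers mixtures and degenerate cohorts", {
  set.seed(33)
  mech <- sample(c("MMEJ", "NHEJ", "MMBIR"), 2000, replace = TRUE,
                 prob = c(0.45, 0.45, 0.10))
  feats <- simulate_junction_features(mech)
  jx <- make_junctions(posA = seq_len(2000) * 10000L,
                       posB = seq_len(2000) * 10000L + 500L,
                       homology_len = feats$homology_len,
                       insertion_len = feats$insertion_len)
  prof <- mechanism_profile(jx)
  expect_lt(abs(prof$mmej_nhej - 0.90), 0.02)

  single <- mechanism_profile(jx[1, ])
  expect_true(all(unlist(single[, c("MMEJ", "NHEJ", "MMBIR")]) %in%
                    c(0, 1)))
  allbir <- simulate_junction_features(rep("MMBIR", 50))
  jb <- make_junctions(posA = 1:50 * 100000L, posB = 1:50 * 100000L + 9L,
                       homology_len = allbir$homology_len,
                       insertion_len = allbir$insertion_len)
  expect_equal(mechanism_profile(jb)$mmej_nhej, 0)
})
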