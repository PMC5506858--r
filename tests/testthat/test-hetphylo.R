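# Heterogeneity partitioning, overlap fractions, discovery curves,
# detection power and recurrence phylogenies.

pm <- function(...) {
  # presence matrix from named logical vectors over a mutation universe
  rows <- list(...)
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(rows)
  colnames(mat) <- paste0("m", seq_len(ncol(mat)))
  mat
}

test_that("mutation partition assigns each event to exactly one category", {
  # identical samples -> all ubiquitous
  mut <- dplyr::bind_rows(
    make_mutations(sample_id = "S1", pos = 1:5 * 10L),
    make_mutations(sample_id = "S2", pos = 1:5 * 10L))
  part <- partition_mutations(mut)
  expect_equal(part$n_ubiquitous, 5)
  expect_equal(part$n_shared, 0)
  expect_equal(part$n_private, 0)

  # disjoint samples -> all private
  dis <- dplyr::bind_rows(
    make_mutations(sample_id = "S1", pos = 1:5 * 10L),
    make_mutations(sample_id = "S2", pos = 6:9 * 10L))
  part2 <- partition_mutations(dis)
  expect_equal(part2$n_private, 9)

  # 3 samples, one mutation in exactly two -> shared
  tri <- dplyr::bind_rows(
    make_mutations(sample_id = "S1", pos = c(10L, 20L)),
    make_mutations(sample_id = "S2", pos = c(10L, 30L)),
    make_mutations(sample_id = "S3", pos = 40L))
  part3 <- partition_mutations(tri)
  expect_equal(part3$n_shared, 1)   # pos 10 in S1+S2
  expect_equal(part3$n_ubiquitous, 0)
  expect_equal(part3$n_private, 3)
})

test_that("partition counts are conserved", {
  set.seed(12)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    rows <- lapply(seq_len(k), function(i) {
      make_mutations(sample_id = paste0("S", i),
                     pos = sample(1:30, sample(3:15, 1)) * 10L)
    })
    part <- partition_mutations(dplyr::bind_rows(rows))
    expect_equal(part$n_ubiquitous + part$n_shared + part$n_private,
                 part$n_total)
  }
})

test_that("single-sample patients are flagged unanalyzable", {
  part <- partition_mutations(make_mutations(pos = 1:3 * 10L))
  expect_false(part$analyzable)
  expect_true(is.na(part$n_ubiquitous))
})

test_that("pairwise shared fractions cover the denominator variants", {
  a <- paste0("m", 1:10)
  expect_equal(pairwise_shared_fraction(a, a), 1)
  expect_equal(pairwise_shared_fraction(a, paste0("x", 1:4)), 0)
  b <- c(paste0("m", 1:5), paste0("y", 1:5))
  expect_equal(pairwise_shared_fraction(a, b), 5 / 15)
  expect_equal(pairwise_shared_fraction(a, b, "first"), 0.5)
  expect_true(is.na(pairwise_shared_fraction(character(), character())))
})

test_that("discovery curve matches an independent ordering oracle", {
  # identical samples -> flat at 1
  mut <- dplyr::bind_rows(
    make_mutations(sample_id = "S1", pos = 1:4 * 10L),
    make_mutations(sample_id = "S2", pos = 1:4 * 10L))
  expect_equal(discovery_curve(mut)$fraction, c(1, 1))

  # fully private equal-size samples, k = 2 -> (0.5, 1)
  dis <- dplyr::bind_rows(
    make_mutations(sample_id = "S1", pos = 1:4 * 10L),
    make_mutations(sample_id = "S2", pos = 5:8 * 10L))
  expect_equal(discovery_curve(dis)$fraction, c(0.5, 1))

  # k = 4 toy: subset average equals average over all orderings
  set.seed(14)
  rows <- lapply(1:4, function(i) {
    make_mutations(sample_id = paste0("S", i),
                   pos = sample(1:25, sample(4:12, 1)) * 10L)
  })
  mut4 <- dplyr::bind_rows(rows)
  curve <- discovery_curve(mut4)
  samples <- sort(unique(mut4$sample_id))
  keysets <- lapply(samples, function(s) {
    mutation_key(mut4[mut4$sample_id == s, ])
  })
  total <- length(unique(unlist(keysets)))
  perms <- all_perms(4)
  for (m in 1:4) {
    oracle <- mean(apply(perms, 1, function(ord) {
      length(unique(unlist(keysets[ord[seq_len(m)]]))) / total
    }))
    expect_equal(curve$fraction[m], oracle)
  }
  expect_true(all(diff(curve$fraction) >= 0))
  expect_equal(curve$fraction[4], 1)
})

test_that("detection power follows the binomial tail", {
  expect_gte(mutation_detection_power(100, 0.25), 0.9999)
  expect_lt(mutation_detection_power(3, 0.05), 0.001)
  # oracle: direct tail summation
  oracle <- function(depth, af, k = 3) {
    sum(vapply(k:depth, function(x) {
      choose(depth, x) * af^x * (1 - af)^(depth - x)
    }, numeric(1)))
  }
  expect_equal(mutation_detection_power(100, 0.25), oracle(100, 0.25),
               tolerance = 1e-10)
  expect_equal(mutation_detection_power(30, 0.1), oracle(30, 0.1),
               tolerance = 1e-10)
  expect_equal(expected_clonal_af(1, 2, 1), 0.5)
})

test_that("powered set requires purity and filters underpowered sites", {
  mut <- dplyr::bind_rows(
    make_mutations(sample_id = "S1", pos = c(10L, 20L),
                   t_alt_count = 10L, t_depth = 100L),
    make_mutations(sample_id = "S2", pos = 10L,
                   t_alt_count = 10L, t_depth = 100L))
  meta <- make_meta(sample_id = c("S1", "S2"), mean_coverage = 100)
  keys <- powered_set(mut, meta)
  expect_equal(length(keys), 2)

  # shallow coverage in one sample kills the whole patient's set
  meta_shallow <- make_meta(sample_id = c("S1", "S2"),
                            mean_coverage = c(100, 4))
  mut_low <- dplyr::bind_rows(
    make_mutations(sample_id = "S1", pos = 10L, t_depth = 100L,
                   t_alt_count = 10L))
  expect_equal(length(powered_set(mut_low, meta_shallow)), 0)

  meta_na <- meta; meta_na$purity <- NA_real_
  expect_error(powered_set(mut, meta_na), "purity")
})

test_that("neighbor joining recovers dominant overlap structure", {
  set.seed(15)
  # A and B share 90%, C shares 10% with either -> (A,B) cherry
  mat <- pm(A = rep(TRUE, 40), B = rep(TRUE, 40), C = rep(TRUE, 40))
  mat[, ] <- FALSE
  mat["A", 1:20] <- TRUE; mat["B", c(1:18, 21:22)] <- TRUE
  mat["C", c(1:2, 23:40)] <- TRUE
  bt <- build_tree(mat)
  d <- ape::cophenetic.phylo(bt$tree)
  expect_lt(d["A", "B"], d["A", "C"])
  expect_lt(d["A", "B"], d["B", "C"])

  # identical samples form a zero-length cherry
  twin <- pm(A = c(TRUE, TRUE, FALSE), B = c(TRUE, TRUE, FALSE))
  bt2 <- build_tree(twin)
  d2 <- ape::cophenetic.phylo(bt2$tree)
  expect_equal(unname(d2["A", "B"]), 0)
})

test_that("tree construction is invariant to sample input order", {
  set.seed(16)
  mat <- matrix(runif(4 * 30) < 0.4, nrow = 4,
                dimnames = list(c("S1", "S2", "S3", "S4"), NULL))
  colnames(mat) <- paste0("m", 1:30)
  bt1 <- build_tree(mat)
  bt2 <- build_tree(mat[c(3, 1, 4, 2), ])
  expect_equal(ape::cophenetic.phylo(bt1$tree),
               ape::cophenetic.phylo(bt2$tree))
})

test_that("NJ topology matches brute-force least-squares on 4-leaf toys", {
  set.seed(17)
  for (rep in 1:10) {
    # two cherry pairs with heavy within-pair sharing
    n <- 40
    trunk <- runif(n) < 0.3
    pairA <- runif(n) < 0.4; pairB <- runif(n) < 0.4
    mat <- rbind(
      S1 = trunk | pairA | (runif(n) < 0.05),
      S2 = trunk | pairA | (runif(n) < 0.05),
      S3 = trunk | pairB | (runif(n) < 0.05),
      S4 = trunk | pairB | (runif(n) < 0.05))
    colnames(mat) <- paste0("m", seq_len(n))
    bt <- build_tree(mat)
    # brute force: least-squares fit of the three unrooted topologies
    labs <- c("S1", "S2", "S3", "S4")
    dm <- matrix(0, 4, 4, dimnames = list(labs, labs))
    for (i in 1:4) for (j in 1:4) {
      if (i == j) next
      inter <- sum(mat[i, ] & mat[j, ]); uni <- sum(mat[i, ] | mat[j, ])
      dm[i, j] <- 1 - inter / uni
    }
    topos <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
    rss <- vapply(topos, function(tp) {
      # branch params: 4 pendant + 1 internal for ((a,b),(c,d))
      a <- tp[1]; b <- tp[2]; c <- tp[3]; d <- tp[4]
      X <- rbind(
        c(1, 1, 0, 0, 0),  # d(a,b)
        c(1, 0, 1, 0, 1),  # d(a,c)
        c(1, 0, 0, 1, 1),  # d(a,d)
        c(0, 1, 1, 0, 1),  # d(b,c)
        c(0, 1, 0, 1, 1),  # d(b,d)
        c(0, 0, 1, 1, 0))  # d(c,d)
      y <- c(dm[a, b], dm[a, c], dm[a, d], dm[b, c], dm[b, d],
             dm[c, d])
      fit <- stats::lm.fit(X, y)
      sum(fit$residuals^2)
    }, numeric(1))
    best <- topos[[which.min(rss)]]
    # NJ cherry pair among the samples (exclude germline)
    dtree <- ape::cophenetic.phylo(bt$tree)[labs, labs]
    # the least-squares winner pairs best[1] with best[2]
    pair <- labs[best[1:2]]
    other <- setdiff(labs, pair)
    expect_lt(dtree[pair[1], pair[2]],
              min(dtree[pair[1], other[1]], dtree[pair[1], other[2]]))
  }
})

test_that("topology classification separates ladders from shuffled cherries", {
  # perfect ladder in chronological order -> score 1, linear
  ladder <- ape::read.tree(
    text = "(germline:1,(S1:1,(S2:1,(S3:1,S4:1):1):1):1);")
  cl <- classify_topology(ladder, paste0("S", 1:4))
  expect_equal(cl$adjacency_score, 1)
  expect_equal(cl$topology_call, "linear")

  # chronology-shuffled cherries (S1,S3) and (S2,S4) -> branched
  shuffled <- ape::read.tree(
    text = "(germline:1,((S1:0.1,S3:0.1):1,(S2:0.1,S4:0.1):1):1);")
  cl2 <- classify_topology(shuffled, paste0("S", 1:4))
  expect_lt(cl2$adjacency_score, 0.5)
  expect_equal(cl2$topology_call, "branched")
})

test_that("driver vs passenger sharing contrasts via fisher", {
  res <- driver_vs_passenger_overlap(
    shared = c(rep(TRUE, 21), FALSE, rep(TRUE, 18), rep(FALSE, 43)),
    is_driver = c(rep(TRUE, 22), rep(FALSE, 61)))
  expect_equal(unname(res$counts["driver", ]), c(21, 1))
  expect_equal(unname(res$counts["passenger", ]), c(18, 43))
  expect_lt(res$p_value, 0.001)
  expect_equal(res$p_value, fisher_oracle(21, 1, 18, 43),
               tolerance = 1e-8)

  all_shared <- driver_vs_passenger_overlap(
    shared = rep(TRUE, 10), is_driver = rep(c(TRUE, FALSE), 5))
  expect_equal(all_shared$p_value, 1)
  expect_error(driver_vs_passenger_overlap(TRUE, FALSE), "driver")
})

test_that("arm-call profiles can reuse the partition machinery", {
  # SCNA analog: identical arm profiles share fraction 1
  arm_keys <- c("1p:loss", "22q:loss", "17q:gain")
  expect_equal(pairwise_shared_fraction(arm_keys, arm_keys), 1)
})
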