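test_that("profile correlation matches cor.test (Fisher CI, t-based p)", {
  a <- random_zprof(60, seed = 1)
  b <- random_zprof(60, seed = 2)
  est <- correlate_profiles(a, b)
  ct <- cor.test(a, b)
  expect_equal(est$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(est$p, ct$p.value, tolerance = 1e-12)
  expect_equal(c(est$ci_lo, est$ci_hi), as.numeric(ct$conf.int),
               tolerance = 1e-12)
  expect_equal(est$n, 60L)
  expect_true(est$ci_lo <= est$r && est$r <= est$ci_hi)

  # symmetry
  est2 <- correlate_profiles(b, a)
  expect_equal(est2$r, est$r)
  expect_equal(est2$p, est$p)

  # exact linearity and self-correlation are degenerate with |r| = 1
  lin <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)
  expect_warning(self <- correlate_profiles(lin, 2 * lin), "degenerate")
  expect_equal(self$r, 1)
  expect_equal(self$p, 0)
  expect_equal(c(self$ci_lo, self$ci_hi), c(1, 1))

  # correlation only over shared genes, optionally restricted
  est3 <- correlate_profiles(a, b[1:40], gene_subset = names(a)[1:20])
  expect_equal(est3$n, 20L)

  expect_error(correlate_profiles(a[1:3], b[1:3]), ">= 4")
})

test_that("library scoring standardizes correlations and ranks deterministically", {
  # hand-constructed 4-gene library with r = {1, 0, -1}:
  # Z = (r - 0) / population sd 0.8165 = {+1.2247, 0, -1.2247}
  q <- c(A = 1, B = 2, C = 3, D = 4)
  orth <- c(A = 1, B = -1, C = -1, D = 1)   # cor with q is exactly 0
  lib <- structure(list(up = q, flat = orth, down = -q),
                   class = "profile_library")
  tab <- score_library(q, lib, min_overlap = 4)
  expect_equal(tab$Z[match(c("up", "flat", "down"), tab$compound)],
               c(1.224745, 0, -1.224745), tolerance = 1e-6)
  expect_equal(tab$rank_pos[match(c("up", "flat", "down"), tab$compound)],
               c(1L, 2L, 3L))
  expect_equal(tab$compound, c("up", "flat", "down"))  # sorted by rank_pos

  # self-retrieval: the query among random profiles ranks first
  query <- random_zprof(200, seed = 10)
  lib2 <- structure(c(list(itself = query),
                      lapply(1:4, function(i) random_zprof(200, seed = 100 + i))),
                    class = "profile_library")
  names(lib2)[2:5] <- paste0("rand", 1:4)
  tab2 <- score_library(query, lib2, min_overlap = 50)
  expect_equal(tab2$compound[1], "itself")
  expect_equal(tab2$rank_pos[1], 1L)

  # degenerate library: identical correlations
  lib3 <- structure(list(x = q, y = q), class = "profile_library")
  expect_error(score_library(q, lib3, min_overlap = 4), "degenerate")

  # insufficient overlap is an error naming the compound
  expect_error(score_library(query, lib, min_overlap = 4), "flat|up|down")
})

test_that("ranks agree with an independent full-sort brute force", {
  for (seed in 1:5) {
    set.seed(seed)
    M <- sample(3:20, 1)
    query <- random_zprof(100, seed = seed)
    lib <- lapply(seq_len(M), function(i) random_zprof(100, seed * 100 + i))
    names(lib) <- sprintf("c%02d", sample(M))  # scrambled names
    tab <- score_library(query, structure(lib, class = "profile_library"),
                         min_overlap = 50)
    # brute force: plain cor, population-sd standardization, full sort
    r <- vapply(lib, function(z) cor(query, z[names(query)]), 0)
    Z <- (r - mean(r)) / sqrt(mean((r - mean(r))^2))
    ord <- order(-Z, names(lib))
    expected_pos <- stats::setNames(order(ord), names(lib))
    expect_equal(stats::setNames(tab$rank_pos, tab$compound),
                 expected_pos[tab$compound])
    # rank_pos and rank_neg are permutations summing to M + 1 without ties
    expect_setequal(tab$rank_pos, seq_len(M))
    expect_setequal(tab$rank_neg, seq_len(M))
    expect_true(all(tab$rank_pos + tab$rank_neg == M + 1))
  }
})

test_that("permutation-null Z separates a planted compound from noise", {
  set.seed(8)
  query <- random_zprof(300, seed = 8)
  planted <- stats::setNames(0.7 * query + sqrt(1 - 0.49) * rnorm(300),
                             names(query))
  lib <- structure(c(list(hit = planted),
                     lapply(1:3, function(i) random_zprof(300, 800 + i))),
                   class = "profile_library")
  names(lib)[2:4] <- paste0("noise", 1:3)
  set.seed(9)
  tab <- score_library(query, lib, min_overlap = 50,
                       method = "permutation", n_perm = 200)
  expect_equal(tab$compound[1], "hit")
  expect_gt(tab$Z[1], 3)
  expect_true(all(abs(tab$Z[tab$compound != "hit"]) < 3))
})

test_that("sign concordance counts reversals with an exact binomial p", {
  # perfect reversal: every top gene flips sign
  a <- random_zprof(50, seed = 3)
  res <- sign_concordance(a, -a, top_k = 20)
  expect_equal(res$n_opposite, 20L)
  expect_equal(res$p, 2 * 0.5^20)

  # worked example: the bundled lithium/depression top-30 table
  d <- alp_mdd_example()
  alp <- stats::setNames(d$alp_z, d$gene)
  mdd <- stats::setNames(d$mdd_z, d$gene)
  res30 <- sign_concordance(alp, mdd, top_k = 30)
  expect_equal(res30$n_opposite, 24L)
  # independent oracle: exact tail summation, doubled
  p_oracle <- 2 * sum(dbinom(24:30, 30, 0.5))
  expect_equal(res30$p, p_oracle, tolerance = 1e-12)
  expect_equal(res30$p, 1.430906e-3, tolerance = 1e-6)

  # requesting more genes than are shared errors with the available count
  expect_error(sign_concordance(a, -a[1:10], top_k = 20), "10")

  # two-sided p is capped at 1 and lives in (0, 1]
  half <- sign_concordance(c(a[1:10], -a[11:20]), a[1:20], top_k = 10)
  expect_lte(half$p, 1)
  expect_gt(half$p, 0)
})

test_that("opposite-sign counts are Binomial(k, 1/2) under independence", {
  set.seed(21)
  n_opp <- replicate(400, {
    a <- stats::setNames(sample(c(-1, 1), 40, TRUE) * runif(40, 0.5, 3),
                         sprintf("G%02d", 1:40))
    b <- stats::setNames(sample(c(-1, 1), 40, TRUE) * runif(40, 0.5, 3),
                         names(a))
    sign_concordance(a, b, top_k = 40)$n_opposite
  })
  expect_equal(mean(n_opp), 20, tolerance = 0.05)  # 20 +/- 1
  expect_equal(var(n_opp), 10, tolerance = 0.25)
})

test_that("library long-TSV round-trip preserves compound profiles", {
  sim <- simulate_drug_library(random_zprof(40, 6), M = 4, planted = 2,
                               rho = 0.8, seed = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_library(sim$library, path)
  back <- read_library(path)
  expect_equal(names(back), names(sim$library))
  for (nm in names(back))
    expect_equal(back[[nm]], sim$library[[nm]], tolerance = 1e-9)
})
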