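test_that("allele flip negates effect, complements frequency, and is an involution", {
  rec <- list(rsid = "rs560887", ref = "T", alt = "C", eaf = 0.674, beta = 0.067)
  fl <- flip_to_effect_allele(rec, "T")
  expect_equal(fl$beta, -0.067)
  expect_equal(fl$eaf, 0.326)
  expect_identical(fl$alt, "T")
  expect_identical(flip_to_effect_allele(rec, "C"), rec)
  expect_identical(flip_to_effect_allele(fl, "C"), rec)
  expect_error(flip_to_effect_allele(rec, "G"), "mismatch")
})

test_that("palindrome detection covers all pairs and rejects indels", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("T", "C"))
  expect_equal(is_palindromic(c("A", "T", "C"), c("T", "C", "G")),
               c(TRUE, FALSE, TRUE))
  expect_error(is_palindromic("AT", "C"), "unsupported variant")
})

test_that("harmonization aligns outcome to the exposure effect allele", {
  exp <- make_panel(data.frame(rsid = "rs340874", ref = "T", alt = "C",
                               eaf = 0.562, beta = 0.020, pval = 1.69e-13))
  conv <- or_ci_to_log(0.982, 0.969, 0.994)
  out_same <- make_panel(data.frame(rsid = "rs340874", ref = "T", alt = "C",
                                    eaf = 0.562, beta = conv$beta, se = conv$se,
                                    pval = 0.004), trait = "BC", dataset = "OncoArray")
  h <- match_instruments(exp, out_same, palindrome_policy = "keep")
  expect_equal(nrow(h), 1L)
  expect_equal(h$X, 0.020)
  expect_equal(h$Y, -0.0181639706277, tolerance = 1e-9)
  expect_identical(h$effect_allele, "C")
  expect_false(h$flipped)

  # outcome encoded on the opposite allele: flipped flag, Y negated
  out_swap <- make_panel(data.frame(rsid = "rs340874", ref = "C", alt = "T",
                                    eaf = 1 - 0.562, beta = -conv$beta,
                                    se = conv$se, pval = 0.004),
                         trait = "BC", dataset = "OncoArray")
  h2 <- match_instruments(exp, out_swap, palindrome_policy = "keep")
  expect_true(h2$flipped)
  expect_equal(h2$Y, h$Y)

  # unmatched exposure rsid: absent from result, present in audit log
  exp2 <- make_panel(data.frame(rsid = c("rs340874", "rs999"), ref = "T",
                                alt = "C", eaf = 0.5, beta = 0.02, pval = 1e-9))
  h3 <- match_instruments(exp2, out_same, palindrome_policy = "keep")
  expect_equal(h3$rsid, "rs340874")
  expect_true(any(grepl("unmatched\trs999", attr(h3, "audit"))))
})

test_that("flipping the whole outcome panel's encoding leaves instruments invariant", {
  set.seed(11)
  K <- 12
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, K, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  exp <- make_panel(data.frame(rsid = sprintf("rs%02d", 1:K), ref = ref, alt = alt,
                               eaf = runif(K, 0.1, 0.4), beta = rnorm(K, 0, 0.03),
                               pval = 1e-10))
  out_df <- data.frame(rsid = exp$rsid, ref = ref, alt = alt,
                       eaf = exp$eaf, beta = rnorm(K, 0, 0.02), se = 0.01,
                       pval = 0.5)
  out <- make_panel(out_df, trait = "BC", dataset = "o")
  flipped_df <- out_df
  flipped_df$ref <- out_df$alt
  flipped_df$alt <- out_df$ref
  flipped_df$beta <- -out_df$beta
  flipped_df$eaf <- 1 - out_df$eaf
  out_flipped <- make_panel(flipped_df, trait = "BC", dataset = "o")
  h1 <- match_instruments(exp, out, palindrome_policy = "infer_by_freq")
  h2 <- match_instruments(exp, out_flipped, palindrome_policy = "infer_by_freq")
  expect_equal(h1$rsid, h2$rsid)
  expect_equal(h1$Y, h2$Y)
  expect_identical(h1$effect_allele, h2$effect_allele)
  # every effect allele is the exposure alt allele; size bounded by inputs
  expect_identical(h1$effect_allele, exp$alt[match(h1$rsid, exp$rsid)])
  expect_lte(nrow(h1), min(nrow(exp), nrow(out)))
})

test_that("palindromic variants follow the chosen policy", {
  exp <- make_panel(data.frame(rsid = c("rsA", "rsB"), ref = "A", alt = "T",
                               eaf = c(0.20, 0.50), beta = 0.02, pval = 1e-9))
  out <- make_panel(data.frame(rsid = c("rsA", "rsB"), ref = "A", alt = "T",
                               eaf = c(0.21, 0.50), beta = 0.05, se = 0.01,
                               pval = 0.5), trait = "BC", dataset = "o")
  expect_equal(nrow(match_instruments(exp, out, palindrome_policy = "drop")), 0L)
  expect_equal(nrow(match_instruments(exp, out, palindrome_policy = "keep")), 2L)
  h <- match_instruments(exp, out, palindrome_policy = "infer_by_freq")
  expect_equal(h$rsid, "rsA")       # rsB ambiguous at eaf 0.5
  expect_equal(h$Y, 0.05)           # frequencies agree: same orientation
  # frequency pointing at the complemented allele flips the effect
  out2 <- make_panel(data.frame(rsid = "rsA", ref = "A", alt = "T", eaf = 0.80,
                                beta = 0.05, se = 0.01, pval = 0.5),
                     trait = "BC", dataset = "o")
  h2 <- match_instruments(exp, out2, palindrome_policy = "infer_by_freq")
  expect_equal(h2$Y, -0.05)
})

test_that("greedy LD pruning keeps the most significant independent set", {
  p <- make_panel(data.frame(rsid = c("a", "b", "c"), beta = 0.02, eaf = 0.3,
                             pval = c(1e-10, 1e-9, 1e-8)))
  ld0 <- diag(3); dimnames(ld0) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(greedy_ld_prune(p, ld0)$rsid, c("a", "b", "c"))

  ld <- ld0; ld["a", "b"] <- ld["b", "a"] <- 0.5
  expect_equal(greedy_ld_prune(p, ld)$rsid, c("a", "c"))

  # equal-p chain r2(a,b)=r2(b,c)=0.2, r2(a,c)=0: lexicographic tie-break keeps {a, c}
  pc <- make_panel(data.frame(rsid = c("a", "b", "c"), beta = 0.02, eaf = 0.3,
                              pval = 1e-10))
  ldc <- ld0
  ldc["a", "b"] <- ldc["b", "a"] <- 0.2
  ldc["b", "c"] <- ldc["c", "b"] <- 0.2
  expect_equal(greedy_ld_prune(pc, ldc)$rsid, c("a", "c"))

  expect_error(greedy_ld_prune(p, ld0[1:2, 1:2]), "absent from LD")
})

test_that("pruned sets are pairwise independent at the threshold", {
  set.seed(5)
  n <- 20
  ids <- sprintf("v%02d", 1:n)
  m <- matrix(runif(n * n, 0, 0.6), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  p <- make_panel(data.frame(rsid = ids, beta = 0.02, eaf = 0.3,
                             pval = runif(n, 1e-12, 1e-8)))
  for (thr in c(0.1, 0.3, 0.5)) {
    kept <- greedy_ld_prune(p, m, r2_threshold = thr)$rsid
    sub <- m[kept, kept, drop = FALSE]
    diag(sub) <- 0
    expect_lt(max(sub), thr)
  }
})
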