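test_that("contrast construction yields 6 testis and 3 liver zero-sum contrasts", {
  ct <- build_contrasts("testis")
  cl <- build_contrasts("liver")
  expect_equal(ncol(ct), 6)
  expect_equal(ncol(cl), 3)
  expect_equal(unname(colSums(ct)), rep(0, 6))
  expect_equal(unname(colSums(cl)), rep(0, 3))
  expect_setequal(colnames(cl), c("AA-AB", "AA-BB", "AB-BB"))
  expect_true(all(grepl("\\.(EARLY|LATE)$", colnames(ct))))
  expect_error(build_contrasts("brain"), "unknown tissue")
})

test_that("with moderation disabled the fit equals the ordinary weighted t", {
  set.seed(21)
  n <- 10
  lc <- matrix(rnorm(20 * n, 5), 20, n,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:n)))
  w <- matrix(runif(20 * n, 0.5, 2), 20, n)
  des <- cbind(A = rep(1:0, each = 5), B = rep(0:1, each = 5))
  ctr <- matrix(c(1, -1), 2, 1, dimnames = list(c("A", "B"), "A-B"))
  fit <- fit_moderated(lc, w, des, ctr, d0 = 0)
  for (g in 1:20) {
    lmf <- lm(lc[g, ] ~ 0 + des, weights = w[g, ])
    s <- summary(lmf)
    tref <- (coef(lmf)[1] - coef(lmf)[2]) /
      sqrt(s$sigma^2 * sum(c(1, -1) * (s$cov.unscaled %*% c(1, -1))))
    expect_equal(fit$t[g], unname(tref), tolerance = 1e-10)
  }
  expect_equal(attr(fit, "df_residual"), n - 2)
})

test_that("with infinite prior df every posterior variance equals the prior", {
  set.seed(22)
  lc <- matrix(rnorm(50 * 8, 5), 50, 8,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  w <- matrix(1, 50, 8)
  des <- cbind(A = rep(1:0, each = 4), B = rep(0:1, each = 4))
  ctr <- matrix(c(1, -1), 2, 1, dimnames = list(c("A", "B"), "A-B"))
  fit <- fit_moderated(lc, w, des, ctr, d0 = Inf)
  sq <- squeeze_var(attr(fit, "s2"), attr(fit, "df_residual"), d0 = Inf)
  expect_equal(sq$s2_post, rep(sq$s02, 50))
})

test_that("variance squeezing agrees with the independent limma fit", {
  skip_if_not_installed("limma")
  set.seed(23)
  s2 <- exp(rnorm(500, 0, 0.8))
  sq <- squeeze_var(s2, df = 26)
  ref <- limma::squeezeVar(s2, df = 26)
  expect_equal(sq$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(sq$s02, ref$var.prior, tolerance = 1e-6)
  expect_equal(sq$s2_post, ref$var.post, tolerance = 1e-8)
})

test_that("the moderated pipeline matches limma on a weighted fit", {
  skip_if_not_installed("limma")
  sim <- cached_sim(1)
  r <- run_de(sim$counts$testis, sim$meta, "testis")
  lf <- limma::lmFit(r$logcpm, r$design, weights = r$weights)
  lf <- limma::eBayes(limma::contrasts.fit(lf, r$contrasts))
  tref <- as.vector(lf$t)
  expect_equal(r$de$t, tref, tolerance = 1e-8)
  expect_equal(attr(r$de, "d0"), lf$df.prior, tolerance = 1e-6)
})

test_that("null simulations give calibrated raw p-values and no DE calls", {
  sim <- simulate_dataset(sim_config(seed = 31, n_autosomal_genes = 1500,
                                     n_z_genes = 500, n_cis_de = 0, n_trans_de = 0))
  r <- run_de(sim$counts$testis, sim$meta, "testis")
  frac <- mean(r$de$p < 0.05)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
  expect_length(attr(r$de, "de_genes"), 0)
})

test_that("the global rule pools p-values and applies step-up BH", {
  de <- data.frame(gene = paste0("g", 1:4), contrast = "c1",
                   logFC = c(1, -1, 1, -1), t = 0, df_total = 10,
                   p = c(0.01, 0.02, 0.03, 0.04))
  out <- global_decide(de, alpha = 0.05)
  expect_equal(out$adj_p, rep(0.04, 4))  # hand BH: max(i) rescue all to 0.04
  expect_equal(out$decision, c("up", "down", "up", "down"))
  de$p <- rep(1, 4)
  expect_true(all(global_decide(de)$decision == "ns"))
  # monotone: adjusted p never decreases as raw p increases
  set.seed(3)
  de2 <- data.frame(gene = paste0("g", 1:100), contrast = "c1", logFC = 1,
                    t = 0, df_total = 10, p = runif(100))
  out2 <- global_decide(de2)
  o <- order(out2$p)
  expect_true(all(diff(out2$adj_p[o]) >= 0))
  expect_true(all(out2$adj_p >= out2$p))
})

test_that("DE calls are invariant to sample column permutation", {
  sim <- cached_sim(1)
  r1 <- run_de(sim$counts$testis, sim$meta, "testis")
  perm <- sample(ncol(sim$counts$testis$counts))
  cm <- count_matrix(sim$counts$testis$counts[, perm], sim$counts$testis$genes)
  r2 <- run_de(cm, sim$meta, "testis")
  expect_setequal(attr(r1$de, "de_genes"), attr(r2$de, "de_genes"))
})

test_that("planted karyotype effects are recovered with controlled errors", {
  sens <- fdp <- numeric(0)
  for (s in 1:2) {
    sim <- cached_sim(s)
    r <- run_de(sim$counts$testis, sim$meta, "testis")
    truth <- sim$truth$de_genes_by_contrast$testis
    sig <- r$de$decision != "ns"
    istrue <- mapply(function(g, ct) g %in% truth[[ct]], r$de$gene, r$de$contrast)
    fdp <- c(fdp, sum(sig & !istrue) / max(1, sum(sig)))
    sens <- c(sens, mean(unique(unlist(truth)) %in% attr(r$de, "de_genes")))
  }
  expect_true(all(sens >= 0.9))
  expect_true(all(fdp <= 0.1))
})

test_that("expression clustering recovers planted profiles and is well-defined", {
  set.seed(41)
  up <- matrix(rep(c(1, 1, 5, 5), each = 20), 20, 4)
  dn <- matrix(rep(c(5, 5, 1, 1), each = 20), 20, 4)
  m <- rbind(up, dn) + rnorm(160, 0, 0.1)
  rownames(m) <- paste0("g", 1:40); colnames(m) <- paste0("s", 1:4)
  cl <- cluster_de_genes(m, k = 2)
  expect_equal(length(unique(cl[1:20])), 1)
  expect_equal(length(unique(cl[21:40])), 1)
  expect_false(cl[1] == cl[21])
  # duplicated rows always co-cluster
  m2 <- m; m2[2, ] <- m2[1, ]
  cl2 <- cluster_de_genes(m2, k = 5)
  expect_equal(cl2[1], cl2[2], ignore_attr = TRUE)
  expect_equal(unname(cluster_de_genes(m, k = 1)), rep(1L, 40))
  expect_error(cluster_de_genes(m, k = 41), "exceeds")
})
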