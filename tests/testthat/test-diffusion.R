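test_that("weighted networks reduce to A under identity similarities", {
  set.seed(31)
  inst <- rand_instance(5, 4)
  nets <- build_weighted_networks(inst$A, diag(4), diag(5))
  expect_equal(nets$A_d, inst$A)
  expect_equal(nets$A_m, inst$A)
})

test_that("all-ones disease similarity broadcasts row sums", {
  set.seed(32)
  inst <- rand_instance(6, 4)
  nets <- build_weighted_networks(inst$A, matrix(1, 4, 4), diag(6))
  for (i in 1:6) {
    expect_equal(unname(nets$A_d[i, ]), rep(sum(inst$A[i, ]), 4))
  }
})

test_that("weighted networks equal the triple-loop product oracle", {
  set.seed(33)
  inst <- rand_instance(4, 3, allow_negative = TRUE)
  nets <- build_weighted_networks(inst$A, inst$SM_dis, inst$SM_mir)
  A_d <- matrix(0, 4, 3)
  A_m <- matrix(0, 4, 3)
  for (i in 1:4) {
    for (j in 1:3) {
      for (k in 1:3) A_d[i, j] <- A_d[i, j] + inst$A[i, k] * inst$SM_dis[k, j]
      for (k in 1:4) A_m[i, j] <- A_m[i, j] + inst$SM_mir[i, k] * inst$A[k, j]
    }
  }
  expect_equal(unname(nets$A_d), A_d, tolerance = 1e-12)
  expect_equal(unname(nets$A_m), A_m, tolerance = 1e-12)
  expect_error(build_weighted_networks(inst$A, diag(5), diag(4)), "square")
})

test_that("diffusion shares normalise columns and rows with 0/0 -> 0", {
  A_w <- matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE)
  sh <- diffusion_shares(A_w)
  expect_equal(sh$W, matrix(c(0.5, 1, 0.5, 0), 2, 2, byrow = TRUE))

  A_z <- cbind(c(1, 2), c(0, 0))
  shz <- diffusion_shares(A_z)
  expect_equal(shz$W[, 2], c(0, 0))
  expect_false(any(is.nan(shz$W)))

  set.seed(34)
  r <- matrix(runif(24), 6, 4)
  shr <- diffusion_shares(r)
  expect_equal(unname(colSums(shr$W)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(rowSums(shr$M)), rep(1, 6), tolerance = 1e-12)
})

test_that("two-way diffusion matches the per-element loop oracle", {
  set.seed(35)
  for (rep in 1:30) {
    n_m <- sample(2:25, 1)
    n_d <- sample(2:15, 1)
    inst <- rand_instance(n_m, n_d, density = runif(1, 0.1, 0.6))
    # include degenerate instances with empty rows/columns
    if (rep %% 5 == 0) {
      inst$A[1, ] <- 0
      inst$A[, 1] <- 0
    }
    nets <- build_weighted_networks(inst$A, inst$SM_dis, inst$SM_mir)
    got <- two_way_diffusion(inst$A, nets, 0.5, 0.5)$SS
    want <- oracle_diffusion(inst$A, inst$SM_dis, inst$SM_mir, 0.5, 0.5)
    expect_lt(max(abs(unname(got) - want)), 1e-10)
  }
})

test_that("degenerate inputs: zero matrix and single-stream endpoints", {
  A <- matrix(0, 3, 2, dimnames = list(c("m1", "m2", "m3"), c("d1", "d2")))
  nets <- build_weighted_networks(A, diag(2), diag(3))
  expect_equal(unname(two_way_diffusion(A, nets)$SS), matrix(0, 3, 2))

  set.seed(36)
  inst <- rand_instance(6, 5)
  nets <- build_weighted_networks(inst$A, inst$SM_dis, inst$SM_mir)
  # alpha = beta = 1 keeps only the disease-weighted stream
  full <- two_way_diffusion(inst$A, nets, 1, 1)$SS
  nets_d_only <- list(A_d = nets$A_d, A_m = nets$A_d)
  dstream <- two_way_diffusion(inst$A, nets_d_only, 0.5, 0.5)$SS
  expect_equal(full, dstream, tolerance = 1e-12)
})

test_that("scores are invariant to positive rescaling of the similarities", {
  set.seed(37)
  inst <- rand_instance(8, 6)
  base <- score_dataset(inst$A, inst$SM_mir, inst$SM_dis)$SS
  scaled <- score_dataset(inst$A, 3.7 * inst$SM_mir, 0.2 * inst$SM_dis)$SS
  expect_equal(base, scaled, tolerance = 1e-12)
})

test_that("every score entry is affine in alpha and in beta", {
  set.seed(38)
  inst <- rand_instance(7, 5)
  nets <- build_weighted_networks(inst$A, inst$SM_dis, inst$SM_mir)
  s0 <- two_way_diffusion(inst$A, nets, 0, 0.3)$SS
  s5 <- two_way_diffusion(inst$A, nets, 0.5, 0.3)$SS
  s1 <- two_way_diffusion(inst$A, nets, 1, 0.3)$SS
  expect_lt(max(abs(s5 - (s0 + s1) / 2)), 1e-10)

  b0 <- two_way_diffusion(inst$A, nets, 0.3, 0)$SS
  b5 <- two_way_diffusion(inst$A, nets, 0.3, 0.5)$SS
  b1 <- two_way_diffusion(inst$A, nets, 0.3, 1)$SS
  expect_lt(max(abs(b5 - (b0 + b1) / 2)), 1e-10)
})

test_that("end-to-end prediction is deterministic and order-insensitive", {
  d <- generate_synthetic(synthetic_spec(n_mirnas = 16, n_diseases = 8,
                                         n_clusters = 2, n_tissues = 6,
                                         seed = 5))
  dir <- withr::local_tempdir()
  write_synthetic(d, dir)
  paths <- file.path(dir, c("associations.tsv", "expression.tsv", "dags.tsv"))
  s1 <- mda_predict(paths[1], paths[2], paths[3])
  s2 <- mda_predict(paths[1], paths[2], paths[3])
  expect_identical(s1$SS, s2$SS)
  expect_true(all(is.finite(s1$SS)))
  expect_equal(dim(s1$SS), dim(s1$A))

  # permuting input rows changes nothing after realignment by ids
  perm_dir <- withr::local_tempdir()
  assoc <- readLines(paths[1])
  set.seed(40)
  writeLines(sample(assoc), file.path(perm_dir, "associations.tsv"))
  expr <- readr::read_tsv(paths[2], show_col_types = FALSE)
  readr::write_tsv(expr[sample(nrow(expr)), ],
                   file.path(perm_dir, "expression.tsv"))
  file.copy(paths[3], file.path(perm_dir, "dags.tsv"))
  s3 <- mda_predict(file.path(perm_dir, "associations.tsv"),
                    file.path(perm_dir, "expression.tsv"),
                    file.path(perm_dir, "dags.tsv"))
  expect_equal(s3$SS[rownames(s1$SS), colnames(s1$SS)], s1$SS,
               tolerance = 1e-12)

  # composition identity: mda_predict equals the diffusion on its own parts
  direct <- score_dataset(s1$A, s1$SM_mir$S, s1$SM_dis$S)$SS
  expect_identical(s1$SS, direct)
})
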