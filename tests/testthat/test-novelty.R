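norm_mat <- function(values, gene_ids) {
  expression_matrix(values, gene_ids = gene_ids, layer = "normalized")
}

test_that("perturbation obeys the step-size contract", {
  mod <- tiny_model()
  x <- norm_mat(matrix(c(0.3, 0.5, -0.2, 1.1), 2, 2), mod$gene_ids)
  # zero step is the identity
  p0 <- perturb_expression(mod, x, 0, "minus")
  expect_equal(p0$values, x$values)
  for (dir in c("minus", "plus")) {
    p <- perturb_expression(mod, x, 0.1, dir, temperature = 1)
    disp <- p$values - x$values
    expect_true(all(abs(disp) <= 0.1 + 1e-15))
    g <- cellnovelty:::input_gradient(mod, x$values, 1)
    nz <- g != 0
    expect_true(all(abs(abs(disp[nz]) - 0.1) < 1e-12))
    # displacement follows the gradient sign
    expected <- if (dir == "minus") -0.1 * sign(g) else 0.1 * sign(g)
    expect_equal(disp, expected, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("the confidence-raising step raises and the lowering step lowers", {
  mod <- tiny_model()
  x <- norm_mat(matrix(c(0.3, 0.5), 1, 2), mod$gene_ids)
  for (Tt in c(1, 10)) {
    s0 <- cellnovelty:::max_softmax(mod, x, Tt)
    s_minus <- cellnovelty:::max_softmax(
      mod, perturb_expression(mod, x, 1e-3, "minus", Tt), Tt)
    s_plus <- cellnovelty:::max_softmax(
      mod, perturb_expression(mod, x, 1e-3, "plus", Tt), Tt)
    expect_gte(s_minus, s0)
    expect_lte(s_plus, s0)
  }
})

test_that("score modes reduce to each other at epsilon zero", {
  fx <- easy_fixture()
  qn_sub <- cellnovelty:::subset_matrix(fx$qn, 1:50)
  msp <- score_msp(fx$model, qn_sub)
  expect_true(all(abs(score_odin(fx$model, qn_sub, 0, 1) - msp) < 1e-9))
  # SEQ at epsilon 0 is the temperature-matched max softmax
  expect_true(all(abs(
    score_seq(fx$model, qn_sub, 0, 1000) -
      cellnovelty:::max_softmax(fx$model, qn_sub, 1000)) < 1e-9))
  expect_true(all(abs(score_sim(fx$model, qn_sub, 0, 1000) - 0.5) < 1e-9))
})

test_that("scores live in their documented ranges", {
  fx <- easy_fixture()
  qn_sub <- cellnovelty:::subset_matrix(fx$qn, 1:100)
  k <- length(fx$model$class_names)
  msp <- score_msp(fx$model, qn_sub)
  expect_true(all(msp >= 1 / k - 1e-12 & msp <= 1 + 1e-12))
  # brute-force oracle: max over softmax rows
  p <- predict_proba(fx$model, qn_sub)
  expect_equal(unname(msp), unname(apply(p, 1, max)))
  for (s in list(score_odin(fx$model, qn_sub),
                 score_seq(fx$model, qn_sub),
                 score_sim(fx$model, qn_sub))) {
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("ODIN's defining behavior: perturbation raises in-distribution confidence", {
  fx <- easy_fixture()
  typical <- which(!fx$d$query_novel)
  qn_t <- cellnovelty:::subset_matrix(fx$qn, typical)
  odin <- score_odin(fx$model, qn_t, epsilon = 0.01, temperature = 1)
  msp <- score_msp(fx$model, qn_t)
  expect_gte(mean(odin), mean(msp))
})

test_that("sequential composition stays within twice the step size", {
  fx <- easy_fixture()
  qn_sub <- cellnovelty:::subset_matrix(fx$qn, 1:30)
  eps <- 0.05
  m1 <- perturb_expression(fx$model, qn_sub, eps, "minus", 1000)
  m2 <- perturb_expression(fx$model, m1, eps, "plus", 1000)
  expect_true(all(abs(m2$values - qn_sub$values) <= 2 * eps + 1e-12))
})

test_that("score perturbation response is first-order in epsilon", {
  fx <- easy_fixture()
  qn_sub <- cellnovelty:::subset_matrix(fx$qn, 1:50)
  base <- score_odin(fx$model, qn_sub, 0, 1000)
  k_hat <- vapply(c(1e-3, 1e-2), function(eps) {
    mean(abs(score_odin(fx$model, qn_sub, eps, 1000) - base)) / eps
  }, 0)
  expect_gt(k_hat[2] / k_hat[1], 1 / 3)
  expect_lt(k_hat[2] / k_hat[1], 3)
})

test_that("novel calling applies the threshold with the documented semantics", {
  conf <- c(a = 0.9, b = 0.1)
  res <- call_novel(conf, mode = "msp", lambda = 0.5)
  expect_identical(res$is_novel, c(FALSE, TRUE))
  expect_equal(res$novelty_score, c(0.1, 0.9))
  expect_identical(res$cell_id, c("a", "b"))

  conf2 <- c(0, 0.25, 0.5, 1)
  expect_true(all(call_novel(conf2, lambda = 0)$is_novel))
  expect_identical(call_novel(conf2, lambda = 1)$is_novel,
                   c(TRUE, FALSE, FALSE, FALSE))

  # raising lambda never adds novel calls: the set shrinks monotonically
  set.seed(5)
  conf3 <- runif(100)
  prev <- rep(TRUE, 100)
  for (lam in seq(0, 1, by = 0.1)) {
    now <- call_novel(conf3, lambda = lam)$is_novel
    expect_true(all(prev | !now))
    prev <- now
  }
})

test_that("non-novel cells are annotated with their predicted type", {
  fx <- easy_fixture()
  conf <- score_msp(fx$model, fx$qn)
  res <- call_novel(conf, mode = "msp", lambda = 0.5, model = fx$model,
                    m = fx$qn)
  expect_true(all(is.na(res$predicted_type[res$is_novel])))
  expect_true(all(res$predicted_type[!res$is_novel] %in%
                    fx$model$class_names))
  # novelty result round trip
  f <- withr::local_tempfile(fileext = ".csv")
  write_novelty(res, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(res))
  expect_true(file.exists(paste0(f, ".params.yaml")))
})
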