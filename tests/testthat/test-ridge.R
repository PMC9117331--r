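test_that("design construction follows the indicator/product rules", {
  # disjoint single targets: identity-like design, no interactions
  p1 <- build_design(data.frame(drug = c("a", "b"),
                                target = c("T1", "T2")))
  expect_equal(dim(p1$x), c(2, 2))
  expect_equal(unname(p1$x), diag(2))
  expect_false(any(p1$interaction))
  # a drug hitting two targets gets the product column
  p2 <- build_design(data.frame(drug = c("a", "a", "b"),
                                target = c("T1", "T2", "T1")))
  expect_equal(colnames(p2$x), c("T1", "T2", "T1:T2"))
  expect_equal(unname(p2$x["a", ]), c(1, 1, 1))
  expect_equal(unname(p2$x["b", ]), c(1, 0, 0))
  expect_error(build_design(data.frame(drug = "a", target = "T1"),
                            response = c(zzz = 1)), "missing for")
  expect_error(build_design(list(a = character())), "empty target")
})

test_that("closed-form solution matches OLS, the textbook shrinkage, and limits", {
  # OLS limit at lambda = 0
  set.seed(1)
  x <- rbinom(10, 1, 0.5); y <- 2 * x + rnorm(10, sd = 0.1)
  prob <- structure(list(x = cbind(T1 = x), y = y, interaction = FALSE,
                         targets = "T1"), class = "ridge_problem")
  f0 <- ridge_solve(prob, 0)
  expect_equal(unname(coef(f0)["T1"]), unname(coef(lm(y ~ x))["x"]),
               tolerance = 1e-10)
  # raw penalized least squares (no intercept): beta = sum(xy)/(sum(x^2)+lambda)
  prob2 <- structure(list(x = cbind(T1 = c(1, 1)), y = c(1, 1),
                          interaction = FALSE, targets = "T1"),
                     class = "ridge_problem")
  f2 <- ridge_solve(prob2, 2, intercept = FALSE)
  expect_equal(unname(coef(f2)["T1"]), 0.5)
  # extreme shrinkage
  fbig <- ridge_solve(prob, 1e9)
  expect_lt(abs(coef(fbig)["T1"]), 1e-6)
  # collinear columns are singular at lambda = 0
  prob3 <- structure(list(x = cbind(T1 = x, T2 = x), y = y,
                          interaction = c(FALSE, FALSE), targets = c("T1", "T2")),
                     class = "ridge_problem")
  expect_error(ridge_solve(prob3, 0), "singular")
})

test_that("solution agrees with a numerical minimizer of the penalized loss", {
  set.seed(2)
  for (rep in 1:10) {
    x <- matrix(rbinom(20, 1, 0.5), 5, 4,
                dimnames = list(NULL, paste0("T", 1:4)))
    y <- rnorm(5)
    prob <- structure(list(x = x, y = y,
                           interaction = c(FALSE, FALSE, TRUE, TRUE),
                           targets = paste0("T", 1:4)),
                      class = "ridge_problem")
    lam <- runif(1, 0.5, 3); v <- sample(c(1, 4, 16), 1)
    fit <- ridge_solve(prob, lam, v)
    obj <- function(b) {
      pred <- drop(x %*% b[-1]) + b[1]
      sum((y - pred)^2) + lam * sum(ifelse(prob$interaction, v, 1) * b[-1]^2)
    }
    num <- optim(rep(0, 5), obj, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-15))
    expect_equal(unname(coef(fit)), num$par, tolerance = 1e-6)
  }
})

test_that("shrinkage is monotone in lambda and v = 1 matches reference ridge", {
  set.seed(3)
  x <- matrix(rbinom(60, 1, 0.4), 20, 3,
              dimnames = list(NULL, paste0("T", 1:3)))
  y <- drop(x %*% c(1, -2, 0.5)) + rnorm(20, sd = 0.3)
  prob <- structure(list(x = x, y = y, interaction = rep(FALSE, 3),
                         targets = paste0("T", 1:3)),
                    class = "ridge_problem")
  lams <- c(0.01, 0.1, 1, 10, 100)
  norms <- vapply(lams, function(l)
    sqrt(sum(coef(ridge_solve(prob, l))[-1]^2)), 0)
  expect_true(all(diff(norms) <= 1e-12))
  skip_if_not_installed("glmnet")
  # glmnet applies its penalty on the internally y-standardized scale:
  # our loss RSS + lambda*|beta|^2 maps to lambda_glmnet = lambda*sd_n(y)/n
  n <- nrow(x)
  sdy <- sqrt(mean((y - mean(y))^2))
  g <- glmnet::glmnet(x, y, alpha = 0, lambda = sdy / n,
                      standardize = FALSE, thresh = 1e-20, maxit = 1e7)
  ours <- coef(ridge_solve(prob, 1))
  expect_equal(unname(ours[-1]), unname(as.numeric(coef(g))[-1]),
               tolerance = 1e-6)
})

test_that("cross-validation drops interactions when none are planted", {
  set.seed(4)
  n <- 60
  x <- cbind(T1 = rbinom(n, 1, 0.5), T2 = rbinom(n, 1, 0.5))
  tg <- do.call(rbind, lapply(seq_len(n), function(i) {
    ts <- c("T1", "T2")[c(x[i, 1] == 1, x[i, 2] == 1)]
    if (!length(ts)) ts <- "T1"
    data.frame(drug = paste0("d", i), target = ts)
  }))
  prob <- build_design(tg)
  xb <- prob$x[, c("T1", "T2")]
  y <- drop(xb %*% c(2, -1.5)) + rnorm(n, sd = 0.2)  # no interaction effect
  fit <- cv_select(prob, seed = 9, y = y)
  expect_true(fit$interactions_dropped)
  eff <- target_effects(fit)
  expect_equal(sort(eff$target), c("T1", "T2"))
  expect_equal(eff$effect[eff$target == "T1"], 2, tolerance = 0.3)
})

test_that("a strong planted interaction keeps an interior penalty", {
  set.seed(5)
  n <- 80
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  tg <- do.call(rbind, lapply(seq_len(n), function(i) {
    ts <- c("T1", "T2")[c(x1[i] == 1, x2[i] == 1)]
    if (!length(ts)) ts <- sample(c("T1", "T2"), 1)
    data.frame(drug = paste0("d", i), target = ts)
  }))
  prob <- build_design(tg)
  y <- drop(prob$x %*% c(1, -1, 4)[match(colnames(prob$x),
                                         c("T1", "T2", "T1:T2"))]) +
    rnorm(n, sd = 0.2)
  fit <- cv_select(prob, seed = 9, y = y)
  expect_false(fit$interactions_dropped)
  expect_lt(fit$v, 2^30)
  b_int <- coef(fit)["T1:T2"]
  expect_gt(unname(b_int), 0)   # sign of the planted interaction recovered
})

test_that("fold assignment and selection are deterministic given the seed", {
  set.seed(6)
  tg <- data.frame(drug = rep(paste0("d", 1:12), each = 1),
                   target = sample(c("T1", "T2", "T3"), 12, TRUE))
  prob <- build_design(tg)
  y <- rnorm(12)
  a <- cv_select(prob, seed = 3, y = y)
  b <- cv_select(prob, seed = 3, y = y)
  expect_equal(a$lambda, b$lambda)
  expect_equal(a$v, b$v)
  expect_equal(coef(a), coef(b))
})

test_that("planted per-target effects are recovered on an orthogonal design", {
  set.seed(7)
  n_t <- 6; reps <- 8
  tg <- data.frame(drug = paste0("d", seq_len(n_t * reps)),
                   target = rep(paste0("T", 1:n_t), reps))
  prob <- build_design(tg)
  beta <- seq(-2, 3, length.out = n_t)
  y <- drop(prob$x %*% beta) + rnorm(n_t * reps, sd = 0.1)
  fit <- cv_select(prob, seed = 1, y = y)
  eff <- target_effects(fit)
  est <- eff$effect[match(paste0("T", 1:n_t), eff$target)]
  expect_gt(cor(est, beta), 0.95)
})
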