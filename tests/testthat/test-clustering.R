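test_that("kmeans_assign matches the exhaustive nearest-center scan", {
  expect_equal(kmeans_assign(0.2, c(0.1, 0.9)), 1L)
  expect_equal(kmeans_assign(0.5, c(0.4, 0.6)), 1L)  # tie -> lower index
  set.seed(7)
  x <- runif(100)
  ctr <- c(0.2, 0.5, 0.9)
  expect_equal(kmeans_assign(x, ctr), naive_assign(x, ctr))
  expect_error(kmeans_assign(numeric(0), ctr), "empty")
  expect_error(kmeans_assign(x, c(0.5, 0.5)), "distinct")
})

test_that("kmeans_update takes per-cluster means and keeps empty clusters", {
  expect_equal(kmeans_update(c(0.2, 0.4), c(1L, 1L), 1L), 0.3)
  expect_equal(kmeans_update(0.7, 1L, 1L), 0.7)
  expect_equal(kmeans_update(c(0.2, 0.4), c(1L, 1L), 2L, centers = c(0, 0.9)),
               c(0.3, 0.9))
})

test_that("kmeans_cluster recovers separated blobs with monotone objective", {
  set.seed(1)
  x <- c(rnorm(200, 0.2, 0.02), rnorm(300, 0.8, 0.02))
  m <- kmeans_cluster(x, 2)
  expect_equal(sort(m$centers), c(0.2, 0.8), tolerance = 0.01)
  expect_true(all(diff(m$objective_history) <= 1e-9))
  # constant input: k reduced with a warning, no crash
  expect_warning(mc <- kmeans_cluster(rep(0.5, 50), 2), "reduced")
  expect_equal(mc$centers, 0.5)
})

test_that("fcm_memberships implements the printed update rule", {
  # pixel 0, centers (1, 3), m = 2: 1/(1 + (1/3)^2) = 9/10
  expect_equal(as.vector(fcm_memberships(0, c(1, 3), 2)), c(0.9, 0.1))
  # equidistant pixel splits evenly
  expect_equal(as.vector(fcm_memberships(0.5, c(0.4, 0.6), 2)), c(0.5, 0.5))
  # zero distance -> crisp row; two coincident zero distances split equally
  expect_equal(as.vector(fcm_memberships(0.4, c(0.4, 0.9), 2)), c(1, 0))
  expect_error(fcm_memberships(0.4, c(0.4, 0.9), 1), "m must be")
  # row-stochastic for random instances at several fuzziness values
  set.seed(2)
  x <- runif(200)
  for (m_ in c(1.1, 2, 3)) {
    u <- fcm_memberships(x, c(0.1, 0.4, 0.95), m_)
    expect_equal(rowSums(u), rep(1, 200), tolerance = 1e-9)
    expect_true(all(u >= 0 & u <= 1))
  }
})

test_that("fcm_centers is the u^m-weighted mean, reducing to Eq-2 means when crisp", {
  expect_equal(fcm_centers(c(0, 2), matrix(0.5, 2, 2), 2), c(1, 1))
  # crisp memberships reduce to per-cluster means for any m
  u <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_equal(fcm_centers(c(0.1, 0.3, 0.9), u, 3.7), c(0.2, 0.9))
  # brute-force re-summation oracle
  set.seed(3)
  x <- runif(50)
  u <- matrix(runif(150), 50, 3)
  u <- u / rowSums(u)
  m_ <- 2.4
  oracle <- sapply(1:3, function(j) sum(u[, j]^m_ * x) / sum(u[, j]^m_))
  expect_equal(fcm_centers(x, u, m_), oracle, tolerance = 1e-12)
})

test_that("fcm_objective equals the brute-force double sum", {
  # pixels {0,2}, single center 1, full membership, m = 2 -> J = 2
  expect_equal(neuroseg:::.fcm_J(c(0, 2), 1, matrix(1, 2, 1), 2), 2)
  set.seed(4)
  x <- runif(30); ctr <- c(0.2, 0.7)
  u <- fcm_memberships(x, ctr, 2)
  brute <- 0
  for (i in seq_along(x)) for (j in seq_along(ctr))
    brute <- brute + u[i, j]^2 * (x[i] - ctr[j])^2
  expect_equal(neuroseg:::.fcm_J(x, ctr, u, 2), brute, tolerance = 1e-12)
  # zero iff crisp zero-distance assignment
  expect_equal(neuroseg:::.fcm_J(c(0.3, 0.5), c(0.3, 0.5),
                                 rbind(c(1, 0), c(0, 1)), 2), 0)
})

test_that("fcm_cluster recovers phantom tissue intensities", {
  ph <- default_phantom(0.05, 0)
  st <- cached("strip_0.05_0", strip_skull(ph$slice))
  x <- st$slice$pixels[st$brain_mask]
  model <- cached("fcm_brain_0.05_0", fcm_cluster(x, c = 3, m = 2))
  expect_equal(sort(model$centers), c(0.15, 0.45, 0.80), tolerance = 0.05)
  expect_true(model$converged)
  expect_true(all(diff(model$objective_history) <= 1e-9))
  expect_equal(rowSums(model$memberships), rep(1, length(x)), tolerance = 1e-9)
  expect_true(all(model$centers >= min(x) & model$centers <= max(x)))
})

test_that("fcm_cluster convergence tolerance is honest", {
  ph <- default_phantom(0.05, 0)
  st <- cached("strip_0.05_0", strip_skull(ph$slice))
  x <- st$slice$pixels[st$brain_mask]
  model <- cached("fcm_brain_0.05_0", fcm_cluster(x, c = 3, m = 2))
  # one more alternation changes the objective by < 10 * tol
  ctr2 <- fcm_centers(x, model$memberships, 2, model$centers)
  u2 <- fcm_memberships(x, ctr2, 2)
  J1 <- tail(model$objective_history, 1)
  J2 <- neuroseg:::.fcm_J(x, ctr2, u2, 2)
  expect_lt(abs(J2 - J1), 10 * 1e-5 * max(1, J1))
})

test_that("near-hard FCM (m = 1.05) agrees with k-means on separated blobs", {
  set.seed(5)
  x <- c(rnorm(300, 0.2, 0.03), rnorm(300, 0.8, 0.03))
  km <- kmeans_cluster(x, 2)
  fm <- fcm_cluster(x, 2, m = 1.05)
  agree <- mean(neuroseg:::.crisp_labels(fm) == neuroseg:::.crisp_labels(km))
  expect_gte(max(agree, 1 - agree), 0.99)  # label order may differ
})

test_that("naive-loop FCM oracle matches exactly on small instances", {
  set.seed(6)
  for (trial in 1:3) {
    x <- runif(sample(50:200, 1))
    k <- sample(2:4, 1)
    init <- sort(runif(k, 0.1, 0.9))
    mine <- fcm_cluster(x, c = k, m = 2, tol = 1e-15, max_iter = 12L,
                        init_centers = init)
    oracle <- naive_fcm(x, k, 2, n_iter = mine$iterations, centers = init)
    expect_equal(mine$centers, oracle$centers, tolerance = 1e-6)
    expect_equal(mine$memberships, oracle$memberships, tolerance = 1e-6)
  }
})

test_that("permuting initial centers permutes clusters but not tissues", {
  ph <- default_phantom(0.05, 1)
  st <- strip_skull(ph$slice)
  x <- st$slice$pixels[st$brain_mask]
  a <- fcm_cluster(x, 3, 2, init_centers = c(0.2, 0.5, 0.8))
  b <- fcm_cluster(x, 3, 2, init_centers = c(0.8, 0.2, 0.5))
  expect_equal(sort(a$centers), sort(b$centers), tolerance = 1e-6)
  ta <- assign_tissue_labels(a, "gm_wm"); tb <- assign_tissue_labels(b, "gm_wm")
  expect_equal(a$centers[ta[["wm"]]], b$centers[tb[["wm"]]], tolerance = 1e-6)
})

test_that("assign_tissue_labels sorts by intensity and rejects degeneracy", {
  model <- list(centers = c(0.44, 0.14, 0.81))
  lab <- assign_tissue_labels(structure(model, class = "cluster_model"))
  expect_equal(lab, c(csf = 2L, gm = 1L, wm = 3L))
  bad <- structure(list(centers = c(0.4, 0.4, 0.8)), class = "cluster_model")
  expect_error(assign_tissue_labels(bad), class = "neuroseg_degenerate_error")
  tm <- structure(list(centers = c(0.1, 0.5, 0.8, 0.93)),
                  class = "cluster_model")
  expect_equal(assign_tissue_labels(tm, "tumor")[["tumor"]], 4L)
})
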