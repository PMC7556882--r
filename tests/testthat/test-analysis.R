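make_frames <- function(xs, box, labels, types, fe = NULL) {
  frames <- lapply(seq_along(xs), function(i) {
    list(x = xs[[i]], type = as.integer(types), charge = numeric(nrow(xs[[i]])),
         force_evals = if (is.null(fe)) i * 100 else fe[i], step = i)
  })
  structure(frames, class = "md_frames", box = box, type_labels = labels,
            molecule_id = seq_len(nrow(xs[[1]])))
}

test_that("g(r) of a uniform random gas is 1 within stochastic error", {
  set.seed(31)
  n <- 1500
  box <- simulation_box(c(40, 40))
  xs <- lapply(1:4, function(i) matrix(runif(2 * n, 0, 40), n, 2))
  frames <- make_frames(xs, box, "A", rep(1, n))
  rdf <- radial_distribution(frames, "A", r_max = 10, bin_width = 0.25)
  # counting error per bin: sd ~ 1/sqrt(expected pairs)
  npairs <- n * (n - 1) / 2 * 4
  shell <- pi * (rdf$bin_centers + 0.125)^2 - pi * (rdf$bin_centers - 0.125)^2
  sigma <- 1 / sqrt(npairs * shell / 1600)
  expect_true(all(abs(rdf$g - 1) < 4 * sigma))
  expect_lt(abs(mean(rdf$g) - 1), 0.01)
})

test_that("two particles contribute a single bin containing their distance", {
  box <- simulation_box(c(10, 10))
  x <- matrix(c(2, 5, 2 + 1.83, 5), 2, 2, byrow = TRUE)
  frames <- make_frames(list(x), box, "A", c(1, 1))
  rdf <- radial_distribution(frames, "A", r_max = 5, bin_width = 0.1)
  hit <- which(rdf$g > 0)
  expect_length(hit, 1)
  expect_true(abs(rdf$bin_centers[hit] - 1.83) <= 0.05 + 1e-12)
  expect_error(radial_distribution(frames, "A", r_max = 6), "half")
})

test_that("the RDF histogram matches a brute-force R loop", {
  set.seed(32)
  n <- 60
  box <- simulation_box(c(12, 12))
  x <- matrix(runif(2 * n, 0, 12), n, 2)
  frames <- make_frames(list(x), box, c("A", "B"), rep(c(1, 2), n / 2))
  rdf <- radial_distribution(frames, "A", r_max = 6, bin_width = 0.2)
  sel <- which(rep(c(1, 2), n / 2) == 1)
  counts <- numeric(30)
  for (a in seq_along(sel)[-length(sel)]) for (b in (a + 1):length(sel)) {
    dx <- x[sel[a], ] - x[sel[b], ]
    dx <- dx - 12 * round(dx / 12)
    r <- sqrt(sum(dx^2))
    if (r < 6) {
      bin <- floor(r / 0.2) + 1
      counts[bin] <- counts[bin] + 1
    }
  }
  edges <- seq(0, 6, by = 0.2)
  shell <- pi * diff(edges^2)
  expected <- length(sel) * (length(sel) - 1) / 2 * shell / 144
  expect_equal(rdf$g, counts / expected, tolerance = 1e-12)
})

test_that("max_gr_series windows frames and reports increasing eval stamps", {
  set.seed(33)
  n <- 80
  box <- simulation_box(c(15, 15))
  xs <- lapply(1:20, function(i) matrix(runif(2 * n, 0, 15), n, 2))
  frames <- make_frames(xs, box, "A", rep(1, n))
  s <- max_gr_series(frames, "A", window = 5, r_max = 7)
  expect_equal(nrow(s), 4)
  expect_true(all(diff(s$force_evals) > 0))
  # equilibrium frames: series fluctuates about a constant
  expect_lt(sd(s$max_gr) / mean(s$max_gr), 0.5)
  # peak equals a direct block computation
  rdf1 <- radial_distribution(frames[1:5], "A", r_max = 7)
  expect_equal(s$max_gr[1], max(rdf1$g[rdf1$bin_centers > 0.5]))
})

test_that("exponential fits recover known parameters", {
  t <- seq(0, 2000, by = 10)
  y <- 2 + 3 * exp(-t / 500)
  fit <- fit_exponential(data.frame(t, y))
  expect_equal(fit$rate, 1 / 500, tolerance = 1e-6)
  expect_equal(fit$y_inf, 2, tolerance = 1e-6)
  expect_equal(fit$amplitude, 3, tolerance = 1e-5)

  set.seed(34)
  y_noisy <- y * (1 + rnorm(length(y), 0, 0.05))
  fitn <- fit_exponential(data.frame(t = t[1:200], y = y_noisy[1:200]))
  expect_lt(abs(fitn$rate - 1 / 500) / (1 / 500), 0.05)

  expect_error(fit_exponential(data.frame(t = 1:50, y = rep(1, 50))),
               "constant")
  expect_error(fit_exponential(data.frame(t = 1:3, y = c(3, 2, 1))),
               "at least 5")
  expect_error(fit_exponential(data.frame(t = 1:100,
                                          y = seq(1, 5, length.out = 100))),
               "decay")
})

test_that("rate recovery is nearly unbiased over replicates", {
  set.seed(35)
  t <- seq(0, 3000, by = 15)
  k_true <- 1 / 600
  rates <- vapply(1:100, function(i) {
    y <- (1.5 + 2.5 * exp(-k_true * t)) * (1 + rnorm(length(t), 0, 0.05))
    fit_exponential(data.frame(t, y))$rate
  }, numeric(1))
  expect_lt(abs(mean(rates) - k_true) / k_true, 0.02)
})

test_that("speedup ratios propagate uncertainty to first order", {
  f1 <- structure(list(rate = 2e-5, se_rate = 0), class = "relaxation_fit")
  f2 <- structure(list(rate = 1e-5, se_rate = 0), class = "relaxation_fit")
  s <- speedup(f1, f2)
  expect_equal(s$ratio, 2)
  expect_equal(s$se, 0)
  expect_equal(speedup(f1, f1)$ratio, 1)
  f3 <- structure(list(rate = 1e-5, se_rate = 1e-6), class = "relaxation_fit")
  s3 <- speedup(f1, f3)
  expect_equal(s3$se, 2 * 0.1, tolerance = 1e-12)
  expect_error(speedup(f1, structure(list(rate = 0, se_rate = 0),
                                     class = "relaxation_fit")), "> 0")

  # synthetic series pair with known rate ratio
  set.seed(36)
  t <- seq(0, 4000, by = 20)
  mk <- function(k) (1 + 2 * exp(-k * t)) * (1 + rnorm(length(t), 0, 0.03))
  fe <- fit_exponential(data.frame(t, y = mk(1 / 300)))
  fr <- fit_exponential(data.frame(t, y = mk(1 / 900)))
  s <- speedup(fe, fr)
  expect_lt(abs(s$ratio - 3), 4 * s$se)
})

test_that("work-based acceptance estimates match theory", {
  expect_equal(acceptance_from_work(rep(0, 10), 1)$estimate, 1)
  expect_equal(acceptance_from_work(c(0, Inf), 1, n_boot = 0)$estimate, 0.5)

  # Gaussian work: compare against numerical quadrature of E[min(1, e^-w/kT)]
  set.seed(37)
  mu <- 1.2; s <- 1.5; kT <- 1
  w <- rnorm(50000, mu, s)
  est <- acceptance_from_work(w, kT, n_boot = 200)
  theory <- integrate(function(x) pmin(1, exp(-x / kT)) * dnorm(x, mu, s),
                      -Inf, Inf)$value
  expect_lt(abs(est$estimate - theory), 3 * est$se + 3e-3)

  # monotone non-increasing under a positive shift of all samples
  for (shift in c(0.1, 0.5, 2)) {
    expect_lte(acceptance_from_work(w + shift, kT, n_boot = 0)$estimate,
               acceptance_from_work(w, kT, n_boot = 0)$estimate)
  }
})

test_that("work summaries decompose means consistently", {
  log1 <- data.frame(w_total = c(1, 3), w_vdw = c(1, 3),
                     w_coulomb = c(0, 0), w_bonded = c(0, 0))
  ws <- work_summary(log1)
  expect_equal(ws$percent[["vdw"]], 100)
  expect_equal(ws$percent[["coulomb"]], 0)

  set.seed(38)
  wv <- rnorm(200, 0.2, 0.1); wc <- rnorm(200, 0.6, 0.2); wb <- rnorm(200, 0.2, 0.05)
  log2 <- data.frame(w_total = wv + wc + wb, w_vdw = wv, w_coulomb = wc,
                     w_bonded = wb)
  ws2 <- work_summary(log2)
  expect_equal(ws2$percent[["coulomb"]],
               100 * mean(wc) / mean(wv + wc + wb), tolerance = 1e-12)
  expect_equal(sum(ws2$percent), 100, tolerance = 1e-9)
  expect_equal(sum(ws2$histogram$counts), 200)
  # row-wise closure of the produced logs is part of the sampler contract
  expect_true(all(abs(log2$w_total - (log2$w_vdw + log2$w_coulomb + log2$w_bonded)) < 1e-12))
})
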