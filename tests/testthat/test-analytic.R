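test_that("max-reputation density has the order-statistic form and normalizes", {
  u <- reputation_distribution("uniform")
  x <- seq(0, 1, length.out = 101)
  expect_equal(max_reputation_density(u, 3, x), 3 * x^2)
  for (d in all_distributions()) {
    expect_equal(max_reputation_density(d, 1, x), d$pdf(x), label = d$name)
    for (n in c(2, 3, 5, 10)) {
      expect_equal(quad01(function(z) max_reputation_density(d, n, z)), 1,
                   tolerance = 1e-8, label = sprintf("%s n=%d", d$name, n))
    }
  }
})

test_that("first-player income matches direct quadrature and known values", {
  for (n in c(2, 5, 10)) {
    mu <- ipd_model(reputation_distribution("uniform"), n)
    expect_equal(expected_income_first(0, mu), (1 + 5 * n) / (1 + n),
                 tolerance = 1e-10)
    ml <- ipd_model(reputation_distribution("linear_increasing"), n)
    expect_equal(expected_income_first(0, ml), (1 + 10 * n) / (1 + 2 * n),
                 tolerance = 1e-10)
  }
  me <- ipd_model(reputation_distribution("exp_decreasing", a = 5), 1)
  expect_equal(expected_income_first(0, me), 1.730, tolerance = 0.001 / 1.73)

  # dual route: moment-based implementation vs direct quadrature
  set.seed(31)
  for (d in all_distributions()) {
    for (n in c(1, 3, 7)) {
      m <- ipd_model(d, n)
      for (q in stats::runif(3)) {
        expect_equal(expected_income_first(q, m),
                     quad_income_first(q, d, n), tolerance = 1e-8,
                     label = sprintf("%s n=%d", d$name, n))
        expect_equal(expected_income_second(q, m),
                     quad_income_second(q, d, n), tolerance = 1e-8,
                     label = sprintf("%s n=%d", d$name, n))
      }
    }
  }
})

test_that("second-player income has its closed values and equals I1 at n = 1", {
  mu <- ipd_model(reputation_distribution("uniform"), 4)
  expect_equal(expected_income_second(0, mu), 3) # int (4x + 1) dx
  ml <- ipd_model(reputation_distribution("linear_decreasing"), 4)
  expect_equal(expected_income_second(0, ml), 7 / 3) # int (2-2x)(4x+1) dx
  cpo <- pd_payoffs(2, 2, 2, 2, strict = FALSE)
  for (d in all_distributions()[c("uniform", "hump")]) {
    m <- ipd_model(d, 3, cpo)
    expect_equal(expected_income_second(stats::runif(5), m), rep(2, 5))
  }
  for (d in all_distributions()) {
    m1 <- ipd_model(d, 1)
    q <- seq(0, 1, by = 0.25)
    expect_equal(expected_income_first(q, m1), expected_income_second(q, m1),
                 label = d$name)
    expect_equal(total_income(q, m1), 2 * expected_income_first(q, m1),
                 label = d$name)
  }
})

test_that("total income reproduces the known reference points", {
  u <- reputation_distribution("uniform")
  q <- seq(0, 1, length.out = 101)
  expect_equal(total_income(q, ipd_model(u, 1)), 6 - 3 * q, tolerance = 1e-10)
  expect_equal(total_income(1, ipd_model(u, 3)), 6.75, tolerance = 1e-10)
  ld <- ipd_model(reputation_distribution("linear_decreasing"), 1)
  expect_equal(total_income(0, ld), 14 / 3, tolerance = 1e-10)
  expect_equal(total_income(0, ld), 4.667, tolerance = 0.001 / 4.667)
  ed <- ipd_model(reputation_distribution("exp_decreasing", a = 5), 1)
  expect_equal(total_income(0, ed), 3.460, tolerance = 0.001 / 3.460)
})

test_that("quadrature route agrees with the uniform-case closed form", {
  u <- reputation_distribution("uniform")
  q <- seq(0, 1, length.out = 101)
  for (n in 1:10) {
    m <- ipd_model(u, n)
    expect_equal(total_income(q, m), closed_form_income_uniform(q, n),
                 tolerance = 1e-8, label = sprintf("n=%d", n))
  }
  # and with a non-default strict PD matrix
  po <- pd_payoffs(T = 7, R = 4, P = 2, S = 0.5)
  for (n in c(1, 2, 6)) {
    m <- ipd_model(u, n, po)
    expect_equal(total_income(q, m), closed_form_income_uniform(q, n, po),
                 tolerance = 1e-8)
  }
  # spot values of the closed form itself
  expect_equal(closed_form_income_uniform(q, 2),
               (-9 * q^2 + 13 * q + 11) / 3, tolerance = 1e-12)
  expect_equal(closed_form_income_uniform(0.5, 1), 4.5)
})

test_that("quadrature route agrees with the linear-increasing closed form", {
  li <- reputation_distribution("linear_increasing")
  q <- seq(0, 1, length.out = 101)
  for (n in 1:10) {
    m <- ipd_model(li, n)
    expect_equal(total_income(q, m), closed_form_income_linear(q, n),
                 tolerance = 1e-8, label = sprintf("n=%d", n))
  }
  expect_equal(closed_form_income_linear(q, 1), (2 / 3) * (11 - 5 * q),
               tolerance = 1e-12)
  expect_equal(closed_form_income_linear(1, 1), 4)
  expect_equal(closed_form_income_linear(0, 2), 21 / 5)
})

test_that("equal payoffs collapse the income to c (1 + n F(q)^(n-1))", {
  cpo <- pd_payoffs(2.5, 2.5, 2.5, 2.5, strict = FALSE)
  q <- seq(0, 1, length.out = 51)
  for (d in all_distributions()) {
    for (n in c(1, 2, 5)) {
      m <- ipd_model(d, n, cpo)
      sel <- if (n == 1) rep(1, length(q)) else n * d$cdf(q)^(n - 1)
      expect_equal(total_income(q, m), 2.5 * (1 + sel),
                   label = sprintf("%s n=%d", d$name, n))
    }
  }
})

test_that("defector income matches section-4 formulas and grows with n", {
  u <- reputation_distribution("uniform")
  li <- reputation_distribution("linear_increasing")
  expect_equal(defector_income(ipd_model(u, 2)), 11 / 3, tolerance = 1e-10)
  expect_equal(defector_income(ipd_model(u, 10)), 51 / 11, tolerance = 1e-10)
  expect_equal(defector_income(ipd_model(li, 2)), 21 / 5, tolerance = 1e-10)
  for (d in list(u, li)) {
    vals <- vapply(2:10, function(n) defector_income(ipd_model(d, n)), 0)
    expect_true(all(diff(vals) > 0))
    expect_equal(vals[1], total_income(0, ipd_model(d, 2)))
  }
  expect_error(defector_income(ipd_model(u, 1)), "n >= 2")
})

test_that("extremum finder locates interior and boundary extrema", {
  u <- reputation_distribution("uniform")
  ex2 <- find_extrema(ipd_model(u, 2))
  int2 <- ex2[ex2$placement == "interior", ]
  expect_equal(nrow(int2), 1)
  expect_equal(int2$kind, "maximum")
  expect_equal(int2$location, 13 / 18, tolerance = 1e-6 / (13 / 18))
  expect_equal(int2$value, closed_form_income_uniform(13 / 18, 2),
               tolerance = 1e-9)

  ex3 <- find_extrema(ipd_model(u, 3))
  int3 <- ex3[ex3$placement == "interior", ]
  expect_equal(int3$kind, "minimum")
  expect_equal(int3$location, (12 - sqrt(102)) / 18, tolerance = 1e-5)
  b3 <- ex3[ex3$placement == "boundary", ]
  expect_equal(b3$value[b3$location == 1], 6.75, tolerance = 1e-10)
  expect_equal(b3$kind[b3$location == 1], "maximum")

  # monotone curve: boundary extrema only
  ex1 <- find_extrema(ipd_model(u, 1))
  expect_equal(nrow(ex1[ex1$placement == "interior", ]), 0)
  expect_equal(ex1$kind[ex1$location == 0], "maximum")
  expect_equal(ex1$kind[ex1$location == 1], "minimum")

  ee <- find_extrema(ipd_model(reputation_distribution("exp_decreasing"), 2))
  ie <- ee[ee$placement == "interior" & ee$kind == "maximum", ]
  expect_equal(ie$location, 0.297, tolerance = 0.002 / 0.297)
  expect_equal(ie$value, 3.897, tolerance = 0.005 / 3.897)
})

test_that("society summary integrates income against the reputation density", {
  m1 <- ipd_model(reputation_distribution("uniform"), 1)
  s1 <- society_summary(m1)
  expect_equal(s1$expected_income, 4.5, tolerance = 1e-9)
  expect_equal(s1$dispersion, sqrt(3) / 2, tolerance = 1e-8)
  s2 <- society_summary(ipd_model(reputation_distribution("linear_increasing"), 2))
  expect_equal(s2$expected_income, 16 / 3, tolerance = 1e-8)
  expect_true(s2$dispersion >= 0)
})

test_that("income curve and model methods are coherent", {
  m <- ipd_model(reputation_distribution("hump"), 3)
  cur <- income_curve(m, 201)
  expect_true(all(diff(cur$q) > 0))
  expect_true(all(is.finite(cur$income)))
  expect_equal(cur$income, predict(m, cur$q))
  expect_equal(predict(m, 0.4, type = "first"),
               expected_income_first(0.4, m))
  co <- coef(m)
  expect_equal(unname(co[c("n", "T", "R", "P", "S")]), c(3, 5, 3, 1, 0))
  sm <- summary(m, grid_size = 501)
  expect_s3_class(sm$extrema, "extremum_report")
  expect_output(print(sm), "Society income")
})
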