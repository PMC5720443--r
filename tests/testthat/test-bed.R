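sch10 <- fractionation_scheme(10, 3.4, 5.5)

test_that("log survival and repopulation follow the linear-quadratic model", {
  ep <- late_endpoint(2)
  expect_equal(survival_uniform(0, 10, ep), 0)
  expect_equal(survival_uniform(3.4, 10, ep), -0.3 * 34 * 2.7)  # -27.54
  expect_equal(survival_uniform(3.4, 20, ep), 2 * survival_uniform(3.4, 10, ep))

  expect_equal(repopulation_term(acute_endpoint(), 0), 0)
  expect_equal(repopulation_term(late_endpoint(), 100), 0)
  expect_equal(repopulation_term(acute_endpoint(), 5.5), 0.9775, tolerance = 1e-4)
  expect_equal(repopulation_term(acute_endpoint(), 5.5), log(2) * 5.5 / (0.3 * 13))
})

test_that("the endpoint registry carries the published parameter set", {
  reg <- default_endpoints()
  expect_equal(sapply(reg, `[[`, "alpha_beta"),
               c(fibrosis = 2, telangiectasia = 4, erythema = 8,
                 desquamation = 11, breast_carcinoma = 4))
  expect_equal(sapply(reg, `[[`, "includes_repopulation"),
               c(fibrosis = FALSE, telangiectasia = FALSE, erythema = TRUE,
                 desquamation = TRUE, breast_carcinoma = FALSE))
  expect_true(all(sapply(reg, `[[`, "alpha") == 0.3))
  expect_true(all(sapply(reg, `[[`, "teff") == 13))
  expect_true(default_endpoints(carcinoma_repopulation = TRUE)$breast_carcinoma$includes_repopulation)
  expect_error(endpoint_by_name("melanoma"), "registry has")
  expect_equal(endpoint_by_name("fibrosis")$fibrosis$alpha_beta, 2)
})

test_that("conventional BED reproduces closed-form values per endpoint class", {
  # late endpoint: no repopulation subtraction
  b <- bed_conventional(sch10, late_endpoint(2))
  expect_equal(b$value, 34 * (1 + 3.4 / 2))
  expect_equal(b$repopulation_component, 0)
  # acute endpoint: subtraction present
  a <- bed_conventional(sch10, acute_endpoint(8))
  expect_equal(a$value, 34 * (1 + 3.4 / 8) - log(2) * 5.5 / (0.3 * 13))
  expect_gt(a$repopulation_component, 0)
  # agrees with the arbitrary-precision direct evaluation
  expect_equal(a$value,
               oracle_eval(list(list(kind = "bed_conv", d = 3.4, n = 10,
                                     ab = 8, repop = log(2) * 5.5 / (0.3 * 13)))),
               tolerance = 1e-12)
})

test_that("log-sum-exp survival averaging is exact and underflow-proof", {
  expect_equal(neg_log_weighted_survival(1, -12.5), 12.5)
  r <- neg_log_weighted_survival(c(0.5, 0.5), c(-700, -800))
  expect_true(is.finite(r))
  expect_equal(r, 700 + log(2), tolerance = 1e-6)
  # naive double-precision summation would be -log(0) here
  expect_equal(-log(sum(c(0.5, 0.5) * exp(c(-800, -900)))), Inf)
  expect_true(is.finite(neg_log_weighted_survival(c(0.5, 0.5), c(-800, -900))))

  expect_error(neg_log_weighted_survival(c(0.6, 0.6), c(-1, -2)), "sum to 1")
  expect_equal(neg_log_weighted_survival(c(0.6, 0.6), c(-5, -5), renormalize = TRUE), 5)
})

test_that("survival averaging matches the 50-digit oracle on random inputs", {
  set.seed(21)
  tasks <- lapply(1:6, function(i) {
    k <- sample(2:200, 1)
    v <- rgamma(k, 1); v <- v / sum(v)
    ls <- -runif(k, 0, 2500)   # far beyond double-precision underflow
    list(kind = "neg_log_wsum", v = v, ls = ls)
  })
  got <- sapply(tasks, function(t) neg_log_weighted_survival(t$v, t$ls))
  exp <- oracle_eval(tasks)
  expect_equal(got, exp, tolerance = 1e-10)
})

test_that("survival-averaged BED collapses to the conventional BED on a delta dDVH", {
  d <- delta_ddvh(3.35, 0.1)  # bin (3.3, 3.4], midpoint 3.35
  sch <- fractionation_scheme(10, 3.35, 5.5)
  for (ep in list(late_endpoint(2), acute_endpoint(8))) {
    expect_equal(bed_heterogeneous_cc(d, sch, ep)$value,
                 bed_conventional(sch, ep)$value, tolerance = 1e-12)
  }
})

test_that("per-fraction BED relates to the constant case on a single bin", {
  d <- delta_ddvh(3.35, 0.1)
  sch <- fractionation_scheme(10, 3.35, 5.5)
  ep <- late_endpoint(2)
  expect_equal(bed_fraction_ivc(d, sch, ep)$value,
               bed_conventional(sch, ep)$value / 10, tolerance = 1e-12)
  expect_equal(10 * bed_fraction_ivc(d, sch, ep)$value,
               bed_heterogeneous_cc(d, sch, ep)$value, tolerance = 1e-12)
})

test_that("two-bin BED values match the arbitrary-precision direct evaluation", {
  d <- two_bin_ddvh(c(3.0, 3.8))
  ep <- late_endpoint(2)
  expect_equal(bed_heterogeneous_cc(d, sch10, ep)$value,
               oracle_bed_of_ddvh("cc", d, sch10, ep), tolerance = 1e-12)
  expect_equal(bed_fraction_ivc(d, sch10, ep)$value,
               oracle_bed_of_ddvh("fivc", d, sch10, ep), tolerance = 1e-12)
  epa <- acute_endpoint(8)
  expect_equal(bed_fraction_ivc(d, sch10, epa)$value,
               oracle_bed_of_ddvh("fivc", d, sch10, epa), tolerance = 1e-12)
})

test_that("the heterogeneous BED lies within the per-bin BED envelope", {
  for (s in 1:4) {
    d <- random_ddvh(80, seed = s)
    ep <- late_endpoint(c(2, 4, 8, 11)[s])
    mids <- (d$bins$lower + d$bins$upper)[d$bins$volume > 0] / 2
    per_bin <- sapply(mids, function(di)
      bed_conventional(fractionation_scheme(10, di, 5.5), ep)$value)
    h <- bed_heterogeneous_cc(d, sch10, ep)$value
    expect_gte(h, min(per_bin) - 1e-9)
    expect_lte(h, max(per_bin) + 1e-9)
  }
})

test_that("BED is monotone non-decreasing under bin-dose increases", {
  d <- random_ddvh(50, seed = 9)
  shift <- ddvh(data.frame(lower = d$bins$lower + d$bin_width,
                           upper = d$bins$upper + d$bin_width,
                           volume = d$bins$volume),
                d$bin_width, "per_fraction")
  for (ep in list(late_endpoint(2), acute_endpoint(11))) {
    expect_gte(bed_heterogeneous_cc(shift, sch10, ep)$value,
               bed_heterogeneous_cc(d, sch10, ep)$value)
    expect_gte(bed_fraction_ivc(shift, sch10, ep)$value,
               bed_fraction_ivc(d, sch10, ep)$value)
    # uniform axis stretch also raises every bin dose
    expect_gte(bed_heterogeneous_cc(rescale_dose_axis(d, 1.2), sch10, ep)$value,
               bed_heterogeneous_cc(d, sch10, ep)$value)
  }
})

test_that("interfraction totals: identity, inequality and permutation symmetry", {
  ep <- late_endpoint(2)
  # n identical deltas reproduce the conventional BED
  dd <- delta_ddvh(3.35, 0.1)
  sch <- fractionation_scheme(10, 3.35, 5.5)
  expect_equal(bed_total_ivc(rep(list(dd), 10), sch, ep)$value,
               bed_conventional(sch, ep)$value, tolerance = 1e-12)

  # identical multi-bin fractions: total >= constant case, strictly
  d <- two_bin_ddvh()
  tot <- bed_total_ivc(rep(list(d), 10), sch10, ep)$value
  cc <- bed_heterogeneous_cc(d, sch10, ep)$value
  expect_gt(tot, cc)
  # and both match the oracle
  expect_equal(tot, 10 * oracle_bed_of_ddvh("fivc", d, sch10, ep), tolerance = 1e-10)

  # permutation invariance
  xs <- lapply(1:5, function(s) random_ddvh(20, seed = s))
  sch5 <- fractionation_scheme(5, 3.4, 5.5)
  expect_equal(bed_total_ivc(xs, sch5, ep)$value,
               bed_total_ivc(rev(xs), sch5, ep)$value, tolerance = 1e-12)
  expect_error(bed_total_ivc(list(), sch5, ep), "non-empty")
})

test_that("BED functions demand the per-fraction dose axis and full dDVHs", {
  tot <- random_ddvh(10, dose_scale = "total_course")
  expect_error(bed_heterogeneous_cc(tot, sch10, late_endpoint()), "rescale_dose_axis")
  expect_error(bed_fraction_ivc(tot, sch10, late_endpoint()), "rescale_dose_axis")
  frag <- table1_fragment()
  expect_error(bed_heterogeneous_cc(frag, sch10, late_endpoint()), "partial")
})
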