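test_that("noncentrality parameters follow the design formulas", {
  expect_equal(srs_ncp(0, 100), 0)
  expect_equal(srs_ncp(0.01, 3055), 5.554, tolerance = 1e-3)
  expect_equal(srs_ncp(0.05, 400) / srs_ncp(0.05, 100), 2) # sqrt(n) scaling

  expect_equal(eps_ncp(0, 100, 0.2), 0)
  expect_equal(eps_ncp(0.019578, 796, 0.2), 5.5687, tolerance = 1e-4)
  expect_error(eps_ncp(0.1, 101, 0.2), class = "chainpower_domain_error")
  expect_error(srs_ncp(1, 100), class = "chainpower_domain_error")

  # EPS beats SRS throughout the study's parameter range at alpha = 0.2
  for (r2 in c(0.001, 0.01, 0.1, 0.34)) {
    expect_gt(eps_ncp(r2, 200, 0.2), srs_ncp(r2, 200))
  }
})

test_that("power_from_ncp is exact under the null and monotone", {
  for (df in c(10, 198, 1000)) {
    expect_identical(power_from_ncp(0, df, sig_level = 0.05), 0.05)
    expect_identical(power_from_ncp(0, df, sig_level = 2.5e-6), 2.5e-6)
  }

  pows <- power_from_ncp(seq(0.5, 8, by = 0.5), df = 100)
  expect_true(all(diff(pows) > 0)) # increasing in ncp
  expect_gt(power_from_ncp(3, 100, sig_level = 1e-3),
            power_from_ncp(3, 100, sig_level = 1e-6))

  # large-df limit approaches the normal closed form
  ncp <- 2
  normal <- pnorm(ncp - qnorm(1 - 1.25e-6)) + pnorm(-ncp - qnorm(1 - 1.25e-6))
  expect_lt(abs(power_from_ncp(ncp, 1e5) - normal), 1e-4)
  expect_equal(power_from_ncp(ncp, 1e5, normal_approx = TRUE), normal)
  # and the deviation from the limit shrinks with df
  gap <- function(df) abs(power_from_ncp(5, df) -
                            (pnorm(5 - qnorm(1 - 1.25e-6)) +
                               pnorm(-5 - qnorm(1 - 1.25e-6))))
  expect_true(gap(1e3) > gap(1e5) && gap(1e5) > gap(1e7))
  expect_lt(gap(1e7), 1e-5)
})

test_that("level powers are ordered and degenerate cases are exact", {
  pw <- chain_power(anchor_model, n = 200)
  snp_srs <- pw$power[pw$scheme == "srs" & pw$level == "snp"]
  expect_lt(snp_srs, 0.01) # single-SNP test has little power

  for (sc in c("srs", "eps")) {
    p <- pw[pw$scheme == sc, ]
    expect_true(p$power[p$level == "prt"] >= p$power[p$level == "rna"])
    expect_true(p$power[p$level == "rna"] >= p$power[p$level == "snp"])
  }
  # EPS dominates SRS level by level
  wide <- tidyr::pivot_wider(pw[, c("scheme", "level", "power")],
                             names_from = "scheme", values_from = "power")
  expect_true(all(wide$eps >= wide$srs))

  null_pw <- chain_power(chain_model(beta = c(0, 0, 0)), n = 200,
                         sig_level = 0.05)
  expect_true(all(null_pw$power == 0.05))
})

test_that("sample-size inversion brackets the target power", {
  res <- chain_sample_size(anchor_model, scheme = "srs", level = "snp")
  expect_equal(res$n_required, 3055, tolerance = 0.05)
  expect_gte(res$achieved_power, 0.8)
  # one step smaller falls below the target
  below <- chain_power(anchor_model, n = res$n_required - 1, scheme = "srs",
                       level = "snp")
  expect_lt(below$power, 0.8)

  res_eps <- chain_sample_size(chain_model(h2 = 0.001), scheme = "eps",
                               level = "rna")
  expect_equal(res_eps$n_required %% 2, 0)
  expect_equal(res_eps$n_required, 795, tolerance = 0.05)
  below_eps <- chain_power(chain_model(h2 = 0.001), n = res_eps$n_required - 2,
                           scheme = "eps", level = "rna")
  expect_lt(below_eps$power, 0.8)

  expect_error(
    chain_sample_size(chain_model(beta = c(0, 0, 0)), scheme = "srs"),
    class = "chainpower_domain_error"
  )
})

test_that("halving the squared correlation roughly doubles the sample size", {
  for (rho_sq in c(0.002, 0.005, 0.01)) {
    m1 <- chain_model(r_squared = c(rho_sq, 0.5, 0.5))
    m2 <- chain_model(r_squared = c(2 * rho_sq, 0.5, 0.5))
    n1 <- chain_sample_size(m1, scheme = "srs", level = "snp")$n_required
    n2 <- chain_sample_size(m2, scheme = "srs", level = "snp")$n_required
    expect_equal(n1 / n2, 2, tolerance = 0.1)
  }
})

test_that("power and sample-size curves are monotone in the expected direction", {
  grid_h2 <- seq(0, 0.025, by = 0.0025)
  pc <- power_curve(anchor_model, "power_vs_h2", h2 = grid_h2, n = 200)
  expect_s3_class(pc, "chain_power_curve")
  for (sc in c("srs", "eps")) {
    for (lv in c("snp", "rna", "prt")) {
      cur <- pc[pc$scheme == sc & pc$level == lv, ]
      expect_true(all(diff(cur$power[order(cur$h2)]) >= 0))
    }
  }

  pn <- power_curve(anchor_model, "power_vs_n", n = seq(40, 1000, by = 40))
  for (sc in c("srs", "eps")) {
    for (lv in c("snp", "rna", "prt")) {
      cur <- pn[pn$scheme == sc & pn$level == lv, ]
      expect_true(increasing_to_saturation(cur$power[order(cur$n)]))
    }
  }

  nh <- power_curve(anchor_model, "n_vs_h2", h2 = seq(0.001, 0.025, by = 0.004))
  for (sc in c("srs", "eps")) {
    for (lv in c("snp", "rna", "prt")) {
      cur <- nh[nh$scheme == sc & nh$level == lv, ]
      expect_true(all(diff(cur$n_required[order(cur$h2)]) <= 0))
    }
  }

  p <- autoplot(pc)
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(nh), "ggplot")
})
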