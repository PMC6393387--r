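test_that("variance propagation matches hand arithmetic", {
  expect_equal(variance_chain(0.25, c(1, 2, 3))$var_x1, 0.375)

  v <- variance_chain(0.25, anchor_beta)
  expect_equal(v$var_x2, 1.12373, tolerance = 1e-5)
  expect_equal(v$var_x3, 1.57979, tolerance = 1e-5)
  expect_equal(v$var_y, 1.32908, tolerance = 1e-5)

  null_chain <- variance_chain(0.3, c(0, 0, 0))
  expect_equal(
    unlist(null_chain[c("var_x2", "var_x3", "var_y")], use.names = FALSE),
    c(1, 1, 1)
  )

  expect_error(variance_chain(0.7, c(1, 1, 1)), class = "chainpower_domain_error")
  expect_error(variance_chain(0.25, c(1, 1, 1), error_var = c(1, -1, 1)),
               class = "chainpower_domain_error")
})

test_that("mediate correlations and heritability follow the chain algebra", {
  r <- mediate_correlations(0.25, anchor_beta)
  expect_equal(r$r1sq, 0.11010, tolerance = 1e-4)
  expect_equal(r$r2sq, 0.36700, tolerance = 1e-4)
  expect_equal(r$r3sq, 0.24760, tolerance = 1e-4)
  expect_equal(r$h2, 0.01, tolerance = 1e-2)
  expect_equal(r$h2, r$r1sq * r$r2sq * r$r3sq, tolerance = 1e-12)
  expect_lte(r$h2, min(r$r1sq, r$r2sq, r$r3sq))

  broken <- mediate_correlations(0.25, c(0.5, 0, 0.5))
  expect_equal(broken$r2sq, 0)
  expect_equal(broken$h2, 0)
})

test_that("population genotype-trait correlation factorises as r1*r2*r3", {
  withr::with_seed(11, {
    for (i in 1:20) {
      p <- random_params()
      m <- chain_model(maf = p$maf, beta = p$beta, error_var = p$error_var)
      cor_x1_y <- prod(p$beta) * m$variances[["var_x1"]] /
        sqrt(m$variances[["var_x1"]] * m$variances[["var_y"]])
      expect_equal(cor_x1_y, prod(sqrt(m$r_squared)), tolerance = 1e-12)
      expect_equal(m$h2, cor_x1_y^2, tolerance = 1e-12)
    }
  })
})

test_that("level-trait correlations attenuate with distance from the trait", {
  lc <- trait_correlations(c(0.11010, 0.36700, 0.24760))
  expect_equal(lc$snp, 0.01000, tolerance = 1e-3)
  expect_equal(lc$rna, 0.09087, tolerance = 1e-4)
  expect_equal(lc$prt, 0.24760, tolerance = 1e-6)

  expect_error(trait_correlations(c(1, 1, 1)),
               class = "chainpower_domain_error")

  withr::with_seed(5, {
    for (i in 1:25) {
      r <- runif(3, 0.01, 0.99)
      lc <- trait_correlations(r)
      expect_true(lc$prt > lc$rna && lc$rna > lc$snp)
    }
  })
})

test_that("inverse solver recovers slopes from target correlations", {
  b <- params_from_correlations(c(0.1101032, 0.3670052, 0.2475954), maf = 0.25)
  expect_equal(unlist(b, use.names = FALSE), anchor_beta, tolerance = 1e-4)

  expect_equal(
    unlist(params_from_correlations(c(0, 0, 0)), use.names = FALSE),
    c(0, 0, 0)
  )
  expect_error(params_from_correlations(c(0.5, 1, 0.5)),
               class = "chainpower_domain_error")

  # round trip: params -> correlations -> params recovers |beta|
  withr::with_seed(23, {
    for (i in 1:20) {
      p <- random_params()
      r <- mediate_correlations(p$maf, p$beta, p$error_var)
      b2 <- params_from_correlations(c(r$r1sq, r$r2sq, r$r3sq),
                                     maf = p$maf, error_var = p$error_var)
      expect_equal(unlist(b2, use.names = FALSE), abs(p$beta),
                   tolerance = 1e-8)
      # and forward again reproduces the targets
      r2 <- mediate_correlations(p$maf, unlist(b2, use.names = FALSE),
                                 p$error_var)
      expect_equal(r2$h2, r$h2, tolerance = 1e-10)
    }
  })
})

test_that("heritability rescaling uses a common cube-root factor", {
  anchor <- chain_anchor()
  s <- scale_to_heritability(anchor, 0.001)
  expect_equal(c(s$r1sq, s$r2sq, s$r3sq),
               c(0.05111, 0.17035, 0.11493), tolerance = 1e-3)
  expect_equal(s$h2, 0.001, tolerance = 1e-10)

  same <- scale_to_heritability(anchor, prod(anchor))
  expect_equal(c(same$r1sq, same$r2sq, same$r3sq), unname(anchor),
               tolerance = 1e-12)

  zero <- scale_to_heritability(anchor, 0)
  expect_equal(c(zero$r1sq, zero$r2sq, zero$r3sq, zero$h2), c(0, 0, 0, 0))

  # monotone: larger target gives componentwise larger correlations
  grid <- c(0.0005, 0.001, 0.005, 0.01, 0.02)
  rs <- t(vapply(grid, function(h2) {
    unlist(scale_to_heritability(anchor, h2)[1, 1:3], use.names = FALSE)
  }, numeric(3)))
  expect_true(all(diff(rs[, 1]) > 0 & diff(rs[, 2]) > 0 & diff(rs[, 3]) > 0))

  expect_error(scale_to_heritability(anchor, 0.9),
               class = "chainpower_domain_error")
})

test_that("chain_model constructors agree and validate their inputs", {
  m_beta <- chain_model(beta = anchor_beta)
  m_rsq <- chain_model(r_squared = m_beta$r_squared)
  m_h2 <- chain_model(h2 = m_beta$h2)
  expect_equal(m_rsq$beta, m_beta$beta, tolerance = 1e-10)
  expect_equal(m_h2$r_squared, m_beta$r_squared, tolerance = 1e-10)

  expect_error(chain_model(beta = anchor_beta, h2 = 0.01),
               class = "chainpower_usage_error")
  expect_error(chain_model(), class = "chainpower_usage_error")

  td <- tidy(m_beta)
  expect_named(td, c("term", "value"))
  expect_equal(td$value[td$term == "h2"], m_beta$h2)
  gl <- glance(m_beta)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$cor2_prt, m_beta$level_cor[["prt"]])
})
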