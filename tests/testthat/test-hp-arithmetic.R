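# the high-precision arithmetic is the package's own primitive, so its
# field operations and transcendentals are checked against exact identities

test_that("big-float arithmetic satisfies exact identities at full precision", {
  for (limbs in c(10L, 18L)) {
    d <- cyclostat:::cpp_hp_selftest(limbs)
    budget <- -32 * (limbs - 2)  # log2 error budget: all limbs but guards
    expect_lt(d$log2_third, budget)    # (1/3) * 3 == 1
    expect_lt(d$log2_expid, budget)    # exp(1) * exp(-1) == 1
    expect_lt(d$log2_sqrt, budget)     # sqrt(2)^2 == 2
    expect_equal(d$pi_err, 0)          # pi to double precision
    expect_equal(d$ln2_err, 0)         # ln 2 to double precision
    expect_equal(d$log2_big, -Inf)     # 2^4000 / 2^4000 == 1 exactly
    expect_lt(abs(d$log2_expneg), 1e-9) # exp(-700) magnitude, no underflow
  }
})
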