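test_that("fractal fixtures carry their closed-form dimensions", {
  expect_equal(attr(make_fractal("line"), "known_dimension"), 1)
  expect_equal(attr(make_fractal("filled_square"), "known_dimension"), 2)
  expect_equal(attr(make_fractal("sierpinski", 5), "known_dimension"),
               log(3) / log(2))
  expect_equal(attr(make_fractal("koch", 4), "known_dimension"),
               log(4) / log(3))
  # Sierpinski pixel count equals the construction closed form 3^depth
  for (d in c(4, 6))
    expect_identical(sum(make_fractal("sierpinski", d)), as.integer(3^d))
  expect_error(make_fractal("sierpinski", 40), "too deep")
})

test_that("vessel network generator is deterministic and conserves truth", {
  spec <- vessel_network_spec(image_size = 160, n_branches = 3,
                              noise_sd = 5, seed = 123)
  a <- make_vessel_network(spec)
  b <- make_vessel_network(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(sum(a$mask), a$truth$vessel_pixels)
  expect_identical(length(a$truth$branch_tortuosity), 3L)
  expect_true(all(a$truth$branch_tortuosity >= 1))
})

test_that("zero wiggle gives straight vessels with unit tortuosity", {
  net <- make_vessel_network(vessel_network_spec(
    image_size = 160, n_branches = 3, wiggle_amplitude = 0, noise_sd = 0,
    seed = 1))
  expect_true(all(abs(net$truth$branch_tortuosity - 1) < 1e-9))
})

test_that("infeasible network specs are rejected", {
  expect_error(vessel_network_spec(thickness = 0))
  expect_error(make_vessel_network(
    vessel_network_spec(image_size = 64, n_branches = 30)), "do not fit")
})

test_that("cohort generator is deterministic and respects its spec", {
  sp <- cohort_spec(seed = 77)
  a <- make_cohort(sp); b <- make_cohort(sp)
  expect_identical(a, b)
  expect_identical(nrow(a), 34L)
  expect_identical(sum(a$group == "improved"), 17L)
  # outcome labels consistent with the letter-gain rule when constrained
  expect_identical(unname(classify_outcome(a$bcva_baseline, a$bcva_12m)),
                   a$group)
  # truncation bounds respected
  expect_true(all(a$bcva_baseline >= 0 & a$bcva_baseline <= 100))
  expect_true(all(a$bcva_12m >= 0 & a$bcva_12m <= 100))
  expect_true(all(a$sfct > 0))
  expect_true(all(a$vessel_length_density <= a$vessel_density))
  expect_true(all(a$ez_grade %in% 0:1))
  expect_error(cohort_spec(n_per_group = 0), "empty")
})

test_that("generated group means track the spec at moderate n", {
  d <- make_cohort(cohort_spec(n_per_group = c(400, 400), seed = 9))
  gi <- d$group == "improved"
  expect_equal(mean(d$sfct[gi]), 79.97, tolerance = 0.1)
  expect_equal(mean(d$sfct[!gi]), 50.66, tolerance = 0.1)
  expect_equal(mean(d$ez_grade[gi] == 0), 10 / 17, tolerance = 0.15)
  expect_equal(mean(d$ez_grade[!gi] == 0), 4 / 17, tolerance = 0.25)
})

test_that("the default cohort has power for the stated SFCT difference", {
  # printed P = 0.003 at 17 vs 17: the Mann-Whitney should reject in the
  # majority of draws from the stated group parameters
  rej <- vapply(1:60, function(s) {
    d <- make_cohort(cohort_spec(seed = s))
    gi <- d$group == "improved"
    mann_whitney(d$sfct[gi], d$sfct[!gi])$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.5)
})
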