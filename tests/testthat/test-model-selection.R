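# Candidate enumeration, the AICc nesting rule, Akaike weights and the
# collinearity screen.

spec_with <- function(fixed) model_spec("y", "gaussian", fixed = fixed)

term_sets <- function(specs) {
  lapply(specs, function(s) sort(s$fixed))
}

test_that("enumeration respects marginality and includes the null model", {
  cand <- enumerate_candidates(spec_with(c("A", "B", "A:B")))
  expect_length(cand, 5L)
  expect_setequal(
    vapply(term_sets(cand), paste, collapse = "|", FUN.VALUE = ""),
    c("", "A", "B", "A|B", "A|A:B|B"))

  expect_length(enumerate_candidates(spec_with("A")), 2L)
  expect_length(enumerate_candidates(spec_with(c("A", "B"))), 4L)
})

test_that("m exchangeable main effects yield 2^m candidates", {
  for (m in 1:4) {
    sp <- spec_with(LETTERS[seq_len(m)])
    expect_length(enumerate_candidates(sp), 2^m)
  }
  expect_error(enumerate_candidates(spec_with(LETTERS[1:13]), max_candidates = 4096),
               "4096")
})

test_that("the nesting rule retains only models beating their simpler nests", {
  fits <- list(fit_shell(character(), 100.0),
               fit_shell("A", 95.0),
               fit_shell(c("A", "B"), 96.5))
  sel <- select_best(fits)
  expect_equal(sel$table$model[sel$table$retained], "A")
  expect_equal(sum(sel$table$retained), 1L)

  single <- select_best(list(fit_shell("A", 50)))
  expect_true(all(single$table$retained))

  fits2 <- list(fit_shell("A", 95.0), fit_shell("B", 95.5),
                fit_shell(character(), 99))
  sel2 <- select_best(fits2)
  expect_setequal(sel2$table$model[sel2$table$retained], c("A", "B"))
  # an AICc tie between nested models goes to the simpler one
  fits3 <- list(fit_shell("A", 95.0), fit_shell(c("A", "B"), 95.0))
  sel3 <- select_best(fits3)
  expect_equal(sel3$table$model[sel3$table$retained], "A")
})

test_that("the retained set always contains the AICc minimum", {
  set.seed(21)
  for (i in 1:25) {
    specs <- enumerate_candidates(spec_with(c("A", "B", "C")))
    fits <- lapply(specs, function(s) fit_shell(s$fixed, runif(1, 90, 110)))
    sel <- select_best(fits)
    expect_true(sel$table$retained[1L])
    expect_equal(sel$table$delta_aicc[1L], 0)
    w <- sel$table$weight[sel$table$retained]
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
})

test_that("selection is invariant to AICc shifts and candidate order", {
  fits <- list(fit_shell(character(), 100), fit_shell("A", 95.4),
               fit_shell("B", 96.1), fit_shell(c("A", "B"), 97.4))
  base <- select_best(fits)
  shifted <- select_best(lapply(fits, function(f) {
    f$aicc <- f$aicc + 37.5; f
  }))
  expect_equal(base$table$retained, shifted$table$retained)
  expect_equal(base$table$weight, shifted$table$weight, tolerance = 1e-12)
  perm <- select_best(fits[c(3, 1, 4, 2)])
  expect_equal(base$table, perm$table)
})

test_that("Akaike weights follow the closed form", {
  expect_equal(akaike_weights(42), 1)
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  expect_equal(akaike_weights(c(100, 102)), c(0.731059, 0.268941),
               tolerance = 1e-6)
  expect_equal(sum(akaike_weights(c(3, 9, 4.2, 5))), 1, tolerance = 1e-12)
})

test_that("the collinearity screen flags strong Pearson correlations", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4))
  d$z <- 2 * d$x + 1
  scr <- collinearity_screen(d, c("x", "z"))
  expect_equal(scr$r, 1, tolerance = 1e-12)
  expect_true(scr$flagged)

  scr2 <- collinearity_screen(d, c("x", "y"))
  expect_equal(scr2$r, 0.8, tolerance = 1e-12)
  expect_true(scr2$flagged)

  orth <- data.frame(a = c(-1, -1, 1, 1), b = c(-1, 1, -1, 1))
  scr3 <- collinearity_screen(orth, c("a", "b"))
  expect_equal(scr3$r, 0)
  expect_false(scr3$flagged)
})

test_that("factors expand to indicators and own-factor pairs are skipped", {
  d <- data.frame(h = rep(c("eco", "gar", "oak"), each = 4),
                  x = rnorm(12), const = 1)
  scr <- collinearity_screen(d, c("h", "x", "const"))
  expect_false(any(grepl("^h=", scr$var1) & grepl("^h=", scr$var2)))
  expect_equal(attr(scr, "degenerate"), "const")
  expect_true(all(is.na(scr$r[scr$var1 == "const" | scr$var2 == "const"])))
  expect_false(any(scr$flagged[is.na(scr$r)] %in% TRUE))
})
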