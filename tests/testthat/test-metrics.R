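test_that("dominance statistics match hand-computed examples", {
  cells <- make_cells(clone = c(1L, 1L, 1L, 2L))
  cd <- clonal_dominance(cells)
  expect_equal(cd$dominance, 0.75)
  expect_identical(cd$id, 1L)
  expect_equal(clonal_dominance(make_cells(clone = rep(3L, 7)))$dominance, 1)
  expect_equal(clonal_dominance(make_cells(clone = rep(1:4, 3)))$dominance,
               1 / 4)
  # tie breaks to the lowest id
  expect_identical(clonal_dominance(make_cells(clone = c(5L, 2L)))$id, 2L)
  expect_error(clonal_dominance(data.frame(clone_id = integer(0))), "empty")

  lin <- make_cells(clone = 1L,
                    lineage = c(rep(1L, 5), rep(2L, 5), rep(NA, 10)))
  ld <- lineage_dominance(lin)
  expect_equal(ld$dominance, 0.25)
  expect_identical(ld$id, 1L)
  expect_equal(lineage_dominance(make_cells(lineage = rep(9L, 6)))$dominance, 1)
  expect_error(lineage_dominance(make_cells(lineage = rep(NA_integer_, 3))),
               "lineage")

  col <- make_cells(color = c(rep(0L, 6), rep(1L, 3), 2L))
  cc <- color_dominance(col)
  expect_equal(cc$dominance, 0.3)
  expect_identical(cc$color, 1L)
  expect_equal(color_density(col), 0.4)
  allb <- make_cells(color = rep(0L, 5))
  expect_equal(color_dominance(allb)$dominance, 0)
  expect_true(is.na(color_dominance(allb)$color))
  expect_equal(color_density(allb), 0)
  expect_equal(color_density(make_cells(color = rep(2L, 4))), 1)
  # colour tie breaks to the first colour in scheme order
  tie <- make_cells(color = c(rep(1L, 5), rep(2L, 5)))
  expect_identical(color_dominance(tie)$color, 1L)
  sc <- builtin_schemes()$confetti4
  expect_identical(color_dominance(tie, scheme = sc)$color, "YFP")
})

test_that("late-founder lineages are excluded or included as requested", {
  cells <- make_cells(
    lineage = c(1L, 1L, 2L, 9L, 9L, 9L, NA),
    late = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)
  )
  expect_equal(lineage_dominance(cells)$dominance, 2 / 7)
  excl <- lineage_dominance(cells, include_late_founders = TRUE)
  expect_equal(excl$dominance, 3 / 7)
  expect_identical(excl$id, 9L)
})

test_that("the staining threshold is a strict inequality on colour density", {
  expect_true(passes_threshold(list(d = 0.48), 0.40))
  expect_false(passes_threshold(list(d = 0.40), 0.40))
  expect_true(passes_threshold(0.01, 0))
  expect_false(passes_threshold(0, 0))
  expect_error(passes_threshold(0.5, 1.5))
})

test_that("dominant-colour switching compares labels and drops unset ones", {
  r1 <- list(dominant_color = "YFP")
  expect_false(color_switched(r1, list(dominant_color = "YFP")))
  expect_true(color_switched(r1, list(dominant_color = "RFP")))
  expect_true(is.na(color_switched(list(dominant_color = NA), r1)))
})

test_that("all metrics agree with brute-force recounts on fuzzed populations", {
  set.seed(99)
  for (i in 1:1000) {
    cells <- random_population()
    cd <- clonal_dominance(cells)
    o <- oracle_clonal(cells)
    expect_identical(cd$dominance, o$dominance)
    expect_identical(cd$id, o$id)

    co <- color_dominance(cells)
    oc <- oracle_color(cells)
    expect_identical(co$dominance, oc$dominance)
    expect_identical(co$color, oc$color)
    expect_identical(color_density(cells), oracle_density(cells))

    if (any(!is.na(cells$lineage_id))) {
      for (incl in c(FALSE, TRUE)) {
        ld <- lineage_dominance(cells, include_late_founders = incl)
        ol <- oracle_lineage(cells, include_late = incl)
        expect_identical(ld$dominance, ol$dominance)
        expect_identical(ld$id, ol$id)
      }
    }
  }
})

test_that("record invariants hold on fuzzed populations", {
  set.seed(199)
  for (i in 1:300) {
    cells <- random_population()
    rec <- dominance_record(cells, gc_id = i, t = 0)
    expect_identical(rec$pdd, rec$c * rec$d)
    expect_lte(rec$c, rec$d)
    expect_lte(rec$d, 1)
    expect_gte(rec$pdd, 0)
    expect_gte(rec$f, 1 / length(unique(cells$clone_id)))
    # permutation invariance of the whole record
    perm <- cells[sample(nrow(cells)), , drop = FALSE]
    rec2 <- dominance_record(perm, gc_id = i, t = 0)
    expect_equal(rec, rec2)
  }
})
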