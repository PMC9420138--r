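mk_records <- function(mli, x, y) {
  data.frame(record_id = seq_along(mli) - 1L, orig_MLI = mli,
             orig_x = x, orig_y = y, stringsAsFactors = FALSE)
}

test_that("coordinate pairs within the threshold merge to the first pair", {
  r <- mk_records(c("A", "A"), c(0, 0), c(0, 300))
  out <- resolve_coordinates(r, 400)
  expect_equal(out$new_x, c(0, 0))
  expect_equal(out$new_y, c(0, 0))
  expect_equal(out$combine_coords_flag, c("combine", "combine"))
  expect_equal(out$dup_coords_flag, c("dup_coords", "dup_coords"))
  expect_equal(out$num_coords_at_loc, c(2L, 2L))
})

test_that("coordinate pairs beyond the threshold keep both locations", {
  # sqrt(300^2 + 300^2) = 424.26 m > 400
  r <- mk_records(c("B", "B"), c(0, 300), c(0, 300))
  out <- resolve_coordinates(r, 400)
  expect_equal(out$new_x, c(0, 300))
  expect_equal(out$combine_coords_flag, c("keep_separate", "keep_separate"))
  # the boundary itself merges: one rule decides the tie
  r <- mk_records(c("B2", "B2"), c(0, 400), c(0, 0))
  out <- resolve_coordinates(r, 400)
  expect_equal(out$combine_coords_flag, c("combine", "combine"))
})

test_that("single-coordinate MLIs pass through unchanged", {
  r <- mk_records("C", 10, 20)
  out <- resolve_coordinates(r, 400)
  expect_equal(out$dup_coords_flag, "one_coord_set")
  expect_true(is.na(out$combine_coords_flag))
  expect_equal(out$new_x, 10)
})

test_that("duplicate MLIs at one coordinate collapse to the first-seen MLI", {
  r <- mk_records(c("S1", "Z", "S2"), c(10, 99, 10), c(10, 99, 10))
  out <- resolve_mlis(resolve_coordinates(r, 400))
  expect_equal(out$new_MLI, c("S1", "Z", "S1"))
  expect_equal(out$num_MLIs_at_loc, c(2L, 1L, 2L))
  expect_equal(out$dup_MLI_flag, c("dup_MLI", "one_MLI", "dup_MLI"))
})

test_that("first appearance is decided by record order, not name order", {
  # rows 0..7: S4 appears at row 1, before S3 (row 2) and S5 (row 7)
  mli <- c("X", "S4", "S3", "X", "X", "X", "X", "S5")
  r <- mk_records(mli, c(99, rep(30, 2), 99, 99, 99, 99, 30),
                  c(99, rep(30, 2), 99, 99, 99, 99, 30))
  out <- resolve_mlis(resolve_coordinates(r, 400))
  at30 <- out$orig_MLI %in% c("S3", "S4", "S5")
  expect_equal(unique(out$new_MLI[at30]), "S4")
  expect_equal(unique(out$num_MLIs_at_loc[at30]), 3L)
})

test_that("site resolution is idempotent, order-stable and conserving", {
  set.seed(42)
  n <- 60
  r <- mk_records(sample(c("A", "B", "C", "D"), n, TRUE),
                  sample(c(0, 100, 2000), n, TRUE),
                  sample(c(0, 150, 5000), n, TRUE))
  out <- resolve_sites(r, 400)
  expect_equal(nrow(out), n)
  expect_equal(out$orig_MLI, r$orig_MLI)
  expect_equal(out$orig_x, r$orig_x)

  # idempotence: feeding the resolved table back changes nothing
  r2 <- mk_records(out$new_MLI, out$new_x, out$new_y)
  out2 <- resolve_sites(r2, 400)
  expect_equal(out2$new_MLI, out$new_MLI)
  expect_equal(out2$new_x, out$new_x)
  expect_equal(out2$new_y, out$new_y)

  # order stability: shuffling storage order leaves results tied to record_id
  perm <- sample(n)
  out3 <- resolve_sites(r[perm, ], 400)
  out3 <- out3[order(out3$record_id), ]
  expect_equal(out3$new_MLI, out$new_MLI)
  expect_equal(out3$new_x, out$new_x)
})

test_that("site resolution matches the brute-force oracle on a mixed fixture", {
  set.seed(7)
  n <- 80
  r <- mk_records(sample(sprintf("M%d", 1:6), n, TRUE),
                  sample(c(0, 50, 350, 900), n, TRUE),
                  sample(c(0, 120, 360), n, TRUE))
  out <- resolve_sites(r, 400)
  orc <- oracle_resolve_sites(r, 400)
  expect_equal(out$new_x, orc$new_x)
  expect_equal(out$new_y, orc$new_y)
  expect_equal(out$new_MLI, orc$new_MLI)
})
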