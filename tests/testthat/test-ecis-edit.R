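make_plate <- function(n_wells = 4, time = seq(0, 10, by = 0.5),
                       seed = 1) {
  set.seed(seed)
  imp <- sapply(seq_len(n_wells), function(j)
    100 + 10 * j + cumsum(abs(rnorm(length(time)))))
  ecis_dataset(time, imp, paste0("A", seq_len(n_wells)))
}

test_that("cut_time keeps the closed interval and composes", {
  ds <- ecis_dataset(0:3, cbind(A1 = c(1, 2, 3, 4)))
  expect_equal(cut_time(ds, 1, 2)$time, c(1, 2))
  expect_error(cut_time(ds, 5, 4), "smaller")
  expect_error(cut_time(ds, 0.1, 0.9), "fewer than 2")

  plate <- make_plate()
  expect_equal(cut_time(plate, t_max = 2.5)$time, seq(0, 2.5, by = 0.5))
  # nested cuts collapse to the inner interval
  a <- cut_time(cut_time(plate, 1, 8), 2, 5)
  b <- cut_time(plate, 2, 5)
  expect_equal(a$impedance, b$impedance)
  expect_equal(a$time, b$time)
})

test_that("select/delete partition the plate and keep value semantics", {
  plate <- make_plate(8)
  sel <- select_wells(plate, c("A3", "A1"))
  expect_identical(sel$wells, c("A3", "A1"))  # order as given
  del <- delete_wells(plate, c("A3", "A1"))
  expect_identical(del$wells, paste0("A", c(2, 4:8)))  # original order
  expect_setequal(c(sel$wells, del$wells), plate$wells)

  expect_error(select_wells(plate, "Z9"), "unknown")
  expect_warning(delete_wells(plate, c("A8", "Z9")), "Z9")
  two <- select_wells(plate, c("A1", "A2"))
  expect_error(delete_wells(two, c("A1", "A2")), "zero wells")

  # inputs are never mutated
  before <- plate$impedance
  invisible(select_wells(plate, "A1"))
  invisible(delete_wells(plate, "A1"))
  expect_identical(plate$impedance, before)
})

test_that("combine concatenates wells, re-grids, and is associative", {
  p1 <- make_plate(2, seed = 1)
  p2 <- make_plate(3, seed = 2)
  both <- combine_ecis(p1, p2)
  expect_equal(n_wells(both), 5)
  expect_equal(both$time, p1$time)
  # duplicate ids get source suffixes
  expect_true(anyDuplicated(both$wells) == 0)

  p3 <- make_plate(2, seed = 3)
  left <- combine_ecis(combine_ecis(p1, p2), p3)
  right <- combine_ecis(p1, combine_ecis(p2, p3))
  expect_equal(left$impedance, right$impedance, ignore_attr = TRUE)

  # unequal grids: interpolation onto the first grid's common range
  shifted <- make_plate(2, time = seq(0.25, 10.25, by = 0.5), seed = 4)
  m <- combine_ecis(p1, shifted)
  expect_equal(n_wells(m), 4)
  expect_true(min(m$time) >= 0.25 && max(m$time) <= 10)

  far <- make_plate(2, time = seq(20, 30, by = 0.5))
  expect_error(combine_ecis(p1, far), "non-overlapping")
})

test_that("shift_start re-anchors time at zero", {
  ds <- ecis_dataset(2:4, cbind(A1 = c(5, 6, 7)))
  out <- shift_start(ds, 2)
  expect_equal(out$time, c(0, 1, 2))
  expect_error(shift_start(ds, 99), "outside")
})

test_that("trim_extend_leading drops rows and prepends a flat prefix", {
  ds <- ecis_dataset(seq(0, 0.9, by = 0.1),
                     cbind(A1 = c(5, 5, 5, 5, 6, 8, 11, 13, 14, 14)))
  expect_equal(n_timepoints(trim_extend_leading(ds, drop_n = 2)), 8)
  ext <- trim_extend_leading(ds, drop_n = 0, extend_hours = 1)
  expect_equal(n_timepoints(ext), 20)  # 1 h / 0.1 h = 10 extra points
  expect_true(all(ext$impedance[1:10, "A1"] == 5))
  expect_error(trim_extend_leading(ds, drop_n = 10), "at least one")
})
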