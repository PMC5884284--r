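test_that("windowed modes follow the strict-majority rule", {
  lab <- matrix(7L, 1, 16)
  expect_equal(windowed_modes(lab, 16, 50)[1, 1], 7L)
  lab2 <- matrix(c(rep(7L, 9), rep(3L, 7)), 1)
  expect_equal(windowed_modes(lab2, 16, 50)[1, 1], 7L)   # 56.25% > 50
  lab3 <- matrix(c(rep(7L, 8), rep(3L, 8)), 1)
  expect_equal(windowed_modes(lab3, 16, 50)[1, 1], 0L)   # 50% is not > 50
  lab4 <- matrix(c(rep(7L, 6), rep(3L, 6), rep(1L, 4)), 1)
  expect_equal(windowed_modes(lab4, 16, 50)[1, 1], 0L)   # multimodal tie
  expect_error(windowed_modes(matrix(1L, 1, 8), 16, 50), "exceeds")
  # degenerate window: upsilon = 1, rho = 0 is the identity
  m <- matrix(sample(1:5, 24, TRUE), 2, 12)
  expect_equal(windowed_modes(m, 1, 0), m, ignore_attr = TRUE)
})

test_that("assigned mode cells always survive a recount", {
  set.seed(101)
  for (i in 1:30) {
    ups <- sample(c(4, 8, 16), 1)
    rho <- sample(c(25, 50, 75), 1)
    m <- matrix(sample(1:4, 3 * 8 * ups, TRUE), 3)
    wm <- windowed_modes(m, ups, rho)
    for (j in 1:3) for (w in seq_len(ncol(wm))) {
      if (wm[j, w] > 0) {
        seg <- m[j, ((w - 1) * ups + 1):(w * ups)]
        expect_gt(sum(seg == wm[j, w]) / ups * 100, rho)
        # and it is the unique mode
        tab <- table(seg)
        expect_equal(sum(tab == max(tab)), 1L)
      }
    }
  }
})

test_that("TFT windows tile the segment and preserve constant maps", {
  # 1000 ms at 256 Hz with upsilon = 16 -> 16 windows of 62.5 ms
  arr <- array(5L, dim = c(2, 256, 3))
  tft <- build_tft(arr, upsilon = 16, rho = 50)
  expect_equal(dim(tft), c(2L, 16L, 3L))
  expect_true(all(tft == 5L))
  expect_equal(16 / 256 * 1000, 62.5)
  # trailing partial window dropped
  tft2 <- build_tft(array(1L, dim = c(2, 260, 1)), upsilon = 16, rho = 50)
  expect_equal(dim(tft2)[2], 16L)
  # idempotency: windowing an already-windowed map with upsilon 1
  again <- build_tft(unclass(tft), upsilon = 1, rho = 0)
  expect_equal(as.integer(again), as.integer(tft))
})

test_that("segmentation slices labels per condition without recomputation", {
  sched <- speller_schedule(2, 2, isi_ms = 125, fs = 256, epoch_ms = 250, seed = 2)
  n_need <- max(sched$onset_sample) + 64 + 1
  set.seed(111)
  rec <- array(sample(0:3, 2 * n_need * 2, TRUE), dim = c(2, n_need, 2))
  rec <- structure(rec, channels = c("A", "B"), total_bits = 4L,
                   class = "pc_cluster_record")
  stacks <- segment_epochs(rec, sched)
  expect_setequal(names(stacks), c("ERP", "noERP"))
  expect_equal(dim(stacks$ERP)[1], sum(sched$condition == "ERP"))
  expect_equal(dim(stacks$ERP)[3], 64L)  # 250 ms at 256 Hz
  # slicing semantics: epoch e equals the record section it came from
  on <- sched$onset_sample[sched$condition == "ERP"][1]
  expect_equal(stacks$ERP[1, , , ], rec[, (on + 1):(on + 64), ],
               ignore_attr = TRUE)
  # epoch past the end of the record errors
  bad <- sched
  bad$onset_sample[nrow(bad)] <- n_need
  attr(bad, "epoch_window") <- attr(sched, "epoch_window")
  expect_error(segment_epochs(rec, bad), "bounds")
})

test_that("intertrial modes behave like a label-space grand average", {
  # stack: epochs x channels x samples x bands
  st <- array(0L, dim = c(100, 1, 2, 1))
  st[, 1, 1, 1] <- c(rep(9L, 60), rep(4L, 40))   # 60% majority
  st[, 1, 2, 1] <- c(rep(9L, 50), rep(4L, 50))   # exact 50%: unassigned
  st <- structure(st, channels = "A", total_bits = 4L, class = "pc_epoch_stack")
  itcm <- intertrial_modes(st, rho = 50)
  expect_equal(as.integer(itcm[1, 1, 1]), 9L)
  expect_equal(as.integer(itcm[1, 2, 1]), 0L)
  # single epoch: identity
  one <- structure(array(3L, dim = c(1, 2, 5, 1)), channels = c("A", "B"),
                   total_bits = 4L, class = "pc_epoch_stack")
  expect_true(all(intertrial_modes(one) == 3L))
  expect_error(intertrial_modes(structure(array(0L, c(0, 1, 1, 1)),
                                          class = "pc_epoch_stack")))
})

test_that("iTFT is invariant to epoch order and duplication", {
  set.seed(121)
  st <- array(sample(0:3, 20 * 2 * 32 * 2, TRUE), dim = c(20, 2, 32, 2))
  st <- structure(st, channels = c("A", "B"), total_bits = 4L,
                  class = "pc_epoch_stack")
  base <- build_itft(st, upsilon = 8, rho = 50)
  perm <- structure(st[sample(20), , , , drop = FALSE], channels = c("A", "B"),
                    total_bits = 4L, class = "pc_epoch_stack")
  expect_equal(as.integer(build_itft(perm, upsilon = 8, rho = 50)),
               as.integer(base))
  dup <- structure(array(c(st, st), dim = c(40, 2, 32, 2)),
                   channels = c("A", "B"), total_bits = 4L,
                   class = "pc_epoch_stack")
  expect_equal(as.integer(build_itft(dup, upsilon = 8, rho = 50)),
               as.integer(base))
  # all epochs identical and constant: every cell carries that label
  cst <- structure(array(2L, dim = c(5, 2, 32, 1)), channels = c("A", "B"),
                   total_bits = 4L, class = "pc_epoch_stack")
  expect_true(all(build_itft(cst, upsilon = 8, rho = 50) == 2L))
})

test_that("tidy views expose band, window, channel and hex label", {
  arr <- array(c(10L, 5L), dim = c(2, 8, 1))
  tft <- build_tft(arr, upsilon = 2, rho = 0)
  td <- tidy(tft)
  expect_named(td, c("band", "window", "channel", "label"))
  expect_equal(nrow(td), 2 * 4 * 1)
  expect_true(all(td$label %in% c("A", "5")))
})
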