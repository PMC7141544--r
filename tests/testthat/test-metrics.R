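test_that("confusion counts behave on exact and degenerate cases", {
  truth <- random_mask(8, 8, 3, seed = 4)
  cc <- confusion(truth, truth, num_classes = 4L)
  expect_true(all(cc$FP == 0L) && all(cc$FN == 0L))
  expect_true(all(cc$TP + cc$FP + cc$FN + cc$TN == 64L))

  pred <- matrix(0L, 8, 8)
  k <- sum(truth == 1L)
  cc2 <- confusion(pred, truth, num_classes = 4L)
  expect_identical(cc2$FN[cc2$class == 1L], k)
  expect_identical(cc2$TP[cc2$class == 1L], 0L)

  expect_error(confusion(pred, truth[1:4, ]), "shapes differ")
  expect_error(confusion(matrix(7L, 8, 8), truth), "exceed")
})

test_that("confusion equals a per-pixel loop oracle on random masks", {
  for (seed in 1:3) {
    pred <- random_mask(8, 8, 4, seed = seed)
    truth <- random_mask(8, 8, 4, seed = seed + 10)
    got <- confusion(pred, truth, 4L)
    for (c in 0:3) {
      tp <- fp <- fn <- tn <- 0L
      for (i in 1:8) for (j in 1:8) {
        p <- pred[i, j] == c; t <- truth[i, j] == c
        if (p && t) tp <- tp + 1L else if (p) fp <- fp + 1L
        else if (t) fn <- fn + 1L else tn <- tn + 1L
      }
      row <- got[got$class == c, ]
      expect_identical(c(row$TP, row$FP, row$FN, row$TN), c(tp, fp, fn, tn))
    }
  }
})

test_that("scores apply the Acc/J/D formulas and their identity", {
  cc <- data.frame(class = 0L, TP = 2L, FP = 1L, FN = 1L, TN = 2L)
  m <- score(cc, mean_over = "all")
  expect_equal(m$per_class$Acc, 2 / 3)
  expect_equal(m$per_class$J, 1 / 2)
  expect_equal(m$per_class$D, 2 / 3)

  perfect <- score(data.frame(class = 0:1, TP = c(5L, 3L), FP = 0L,
                              FN = 0L, TN = c(3L, 5L)))
  expect_true(all(perfect$per_class[, c("Acc", "J", "D")] == 1))

  # degenerate class absent from both masks is perfect, not 0/0
  degen <- score(data.frame(class = 0L, TP = 0L, FP = 0L, FN = 0L, TN = 9L),
                 mean_over = "all")
  expect_equal(unlist(degen$per_class[, c("Acc", "J", "D")]),
               c(Acc = 1, J = 1, D = 1))
})

test_that("D = 2J/(1+J) holds to 1e-12 on randomized counts", {
  counts <- cxrmesh:::with_seed(99, data.frame(
    class = 0:999,
    TP = sample(0:500, 1000, TRUE), FP = sample(0:500, 1000, TRUE),
    FN = sample(0:500, 1000, TRUE), TN = sample(0:500, 1000, TRUE)))
  m <- score(counts, mean_over = "all")
  expect_lt(max(abs(m$per_class$D - 2 * m$per_class$J /
                      (1 + m$per_class$J))), 1e-12)
  expect_true(all(m$per_class$J <= m$per_class$D + 1e-15))
  expect_lte(m$mean_j, m$mean_d)
})

test_that("swapping prediction and truth transposes FP/FN but fixes J and D", {
  pred <- random_mask(10, 10, 4, seed = 1)
  truth <- random_mask(10, 10, 4, seed = 2)
  a <- confusion(pred, truth); b <- confusion(truth, pred)
  expect_identical(a$FP, b$FN)
  expect_identical(a$FN, b$FP)
  expect_equal(score(a)$per_class[, c("J", "D")],
               score(b)$per_class[, c("J", "D")])
})

test_that("two-fold averaging is the elementwise mean", {
  m1 <- score(confusion(random_mask(6, 6, 4, 1), random_mask(6, 6, 4, 2)))
  expect_equal(twofold_average(m1, m1), m1)

  m2 <- score(confusion(random_mask(6, 6, 4, 3), random_mask(6, 6, 4, 4)))
  avg <- twofold_average(m1, m2)
  expect_equal(avg$per_class$J, (m1$per_class$J + m2$per_class$J) / 2)
  expect_equal(avg$mean_d, (m1$mean_d + m2$mean_d) / 2)
})
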