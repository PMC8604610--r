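test_that("green thresholding returns exactly the qualifying band pixels", {
  fr <- make_test_frame(5, 5, green_at = data.frame(x = c(2, 4), y = c(2, 1)))
  hit <- threshold_green(fr, 205)
  expect_setequal(paste(hit$x, hit$y), c("2 2", "4 1"))
  # inclusive comparison at the threshold itself
  fr2 <- make_test_frame(5, 5, green_at = data.frame(x = 1, y = 1), g = 205L)
  expect_identical(nrow(threshold_green(fr2, 205)), 1L)
  expect_identical(nrow(threshold_green(fr2, 206)), 0L)
  # degenerate threshold 0 returns every pixel in the band
  expect_identical(nrow(threshold_green(fr, 0, band = c(1, 4))), 15L)
  expect_identical(nrow(threshold_green(make_test_frame(4, 4), 205)), 0L)
  expect_error(threshold_green(fr, 205, band = c(3, 3)), "empty")
  expect_error(threshold_green(fr, 205, band = c(0, 9)), "outside")
})

test_that("raising the green threshold never adds pixels", {
  set.seed(21)
  px <- array(sample(0:255, 30 * 30 * 3, TRUE), c(30, 30, 3))
  fr <- new_frame(px)
  counts <- vapply(seq(0, 255, by = 15),
                   function(t) nrow(threshold_green(fr, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("proximity clustering follows single-linkage transitive closure", {
  # one isolated pixel
  one <- proximity_cluster(tibble::tibble(x = 0, y = 0), 2)
  expect_identical(one$cluster, 1L)
  # two nearby + one far pixel
  pts <- tibble::tibble(x = c(0, 0, 10), y = c(0, 1, 10))
  cl <- proximity_cluster(pts, 2)
  expect_same_partition(cl$cluster, c(1L, 1L, 2L))
  # chain links transitively even though the endpoints are 4 apart
  chain <- proximity_cluster(tibble::tibble(x = c(0, 0, 0), y = c(0, 2, 4)), 2)
  expect_identical(unique(chain$cluster), 1L)
  # empty input
  expect_identical(nrow(proximity_cluster(tibble::tibble(x = double(0),
                                                         y = double(0)), 2)),
                   0L)
  expect_error(proximity_cluster(pts, 0), "> 0")
})

test_that("clustering equals the brute-force oracle on random point sets", {
  set.seed(22)
  for (rep in 1:30) {
    n <- sample(1:50, 1)
    pts <- tibble::tibble(x = sample(0:30, n, replace = TRUE),
                          y = sample(0:30, n, replace = TRUE))
    pts <- dplyr::distinct(pts)
    for (thr in c(1, 2, 5)) {
      got <- proximity_cluster(pts, thr)$cluster
      expect_same_partition(got, brute_force_cluster(pts, thr))
      # partition: disjoint and exhaustive by construction of membership
      expect_identical(length(got), nrow(pts))
      expect_false(anyNA(got))
    }
  }
  # non-integer coordinates exercise the pairwise-distance fallback
  set.seed(23)
  pts <- tibble::tibble(x = runif(40, 0, 20), y = runif(40, 0, 20))
  for (thr in c(1.5, 3)) {
    expect_same_partition(proximity_cluster(pts, thr)$cluster,
                          brute_force_cluster(pts, thr))
  }
})

test_that("size filtering keeps clusters within inclusive bounds in order", {
  sizes <- c(64, 65, 510, 511)
  clustered <- purrr::imap(sizes, function(s, i) {
    tibble::tibble(x = seq_len(s), y = i * 1000, g = 255L, cluster = i)
  }) |> purrr::list_rbind()
  kept <- filter_cluster_size(clustered, 65, 510)
  kept_sizes <- dplyr::count(kept, cluster)$n
  expect_identical(kept_sizes, c(65L, 510L))
  expect_identical(unique(kept$cluster), c(2L, 3L))
  # degenerate bounds keep everything; empty input stays empty
  expect_identical(nrow(filter_cluster_size(clustered, 1, .Machine$integer.max)),
                   nrow(clustered))
  expect_identical(nrow(filter_cluster_size(clustered[0, ], 65, 510)), 0L)
  expect_error(filter_cluster_size(clustered, 100, 50), "<=")
})

test_that("centroids are coordinate means and stay inside the bounding box", {
  expect_equal(compute_centroid(tibble::tibble(x = 3, y = 4)),
               c(x = 3, y = 4))
  expect_equal(compute_centroid(tibble::tibble(x = c(0, 2, 0, 2),
                                               y = c(0, 0, 2, 2))),
               c(x = 1, y = 1))
  expect_equal(compute_centroid(tibble::tibble(x = c(0, 0, 0),
                                               y = c(0, 1, 5))),
               c(x = 0, y = 2))
  expect_error(compute_centroid(tibble::tibble(x = double(0), y = double(0))),
               "empty")
  set.seed(24)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    pts <- tibble::tibble(x = sample(0:100, n, TRUE),
                          y = sample(0:100, n, TRUE))
    ctr <- compute_centroid(pts)
    expect_gte(ctr[["x"]], min(pts$x)); expect_lte(ctr[["x"]], max(pts$x))
    expect_gte(ctr[["y"]], min(pts$y)); expect_lte(ctr[["y"]], max(pts$y))
  }
})

test_that("detect_paws recovers rendered blobs and rejects distractors", {
  expect_identical(nrow(detect_paws(make_test_frame(20, 40))), 0L)
  # four paw-sized disks; centroids must land within 1 px of the centers
  fr <- make_test_frame(60, 200, bg = 40L)
  centers <- data.frame(x = c(170, 160, 60, 50), y = c(15, 45, 15, 45))
  for (i in 1:4) {
    fr <- stamp_disk(fr, centers$x[i], centers$y[i], 6, g = 230L)
  }
  det <- detect_paws(fr)
  expect_identical(nrow(det), 4L)
  # sorted by centroid x descending
  expect_identical(det$x, sort(det$x, decreasing = TRUE))
  ord <- order(-centers$x)
  expect_true(all(abs(det$x - centers$x[ord]) <= 1))
  expect_true(all(abs(det$y - centers$y[ord]) <= 1))
  expect_true(all(det$size == 113L))

  # add a sub-minimum speck and a super-maximum streak: still 4 clusters
  px <- unclass(fr)
  px[5:6, 100:101, 2] <- 230L                  # 4-px speck
  px[29:31, 3:190, 2] <- 230L                  # 564-px streak
  det2 <- detect_paws(new_frame(px))
  expect_identical(nrow(det2), 4L)
  expect_equal(det2$x, det$x, tolerance = 1e-12)
})
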