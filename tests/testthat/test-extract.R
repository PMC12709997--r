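test_that("points_from_mask caps and subsamples deterministically", {
  sim <- simulate_root_mask(40, 40,
    blobs = data.frame(centre_x = 20, centre_y = 20, n_pixels = 4),
    seed = 1
  )
  xy <- points_from_mask(sim$mask, subsample_cap = 20000)
  expect_equal(nrow(xy), 4)
  expect_false(attr(xy, "provenance")$subsampled)

  big <- root_mask(matrix(TRUE, 100, 100))
  sub1 <- points_from_mask(big, subsample_cap = 2000, seed = 3)
  sub2 <- points_from_mask(big, subsample_cap = 2000, seed = 3)
  expect_equal(nrow(sub1), 2000)
  expect_identical(sub1, sub2)
  expect_true(attr(sub1, "provenance")$subsampled)
  expect_equal(attr(sub1, "provenance")$n_root_pixels, 10000)
  sub3 <- points_from_mask(big, subsample_cap = 2000, seed = 4)
  expect_false(identical(sub1[, 1], sub3[, 1]))
})

test_that("largest_cluster picks the majority, excludes noise, breaks ties low", {
  xy <- cbind(seq_len(400), seq_len(400))
  lab <- c(rep(1L, 300), rep(2L, 100))
  top <- largest_cluster(xy, lab)
  expect_equal(top$size, 300)
  expect_equal(top$centre_x, mean(1:300))

  expect_null(largest_cluster(xy[1:50, ], rep(0L, 50)))

  # tie: both sizes 10; smaller label must win (verified by checking both)
  lab_tie <- rep(c(3L, 7L), each = 10)
  top_tie <- largest_cluster(xy[1:20, ], lab_tie)
  expect_equal(top_tie$label, 3L)
  expect_equal(top_tie$centre_x, mean(1:10))
  cand_sizes <- c(sum(lab_tie == 3), sum(lab_tie == 7))
  expect_equal(cand_sizes[1], cand_sizes[2])
})

test_that("local density counts the in-image 3x3 neighbourhood", {
  px <- matrix(FALSE, 7, 9)
  px[4, 5] <- TRUE # isolated
  m <- root_mask(px)
  expect_equal(local_density(m)[4, 5], 1)

  block <- root_mask(matrix(TRUE, 7, 9))
  ld <- local_density(block)
  expect_equal(ld[4, 5], 9) # interior
  expect_equal(ld[1, 5], 6) # edge, non-corner: 3x2 in-image window
  expect_equal(ld[1, 1], 4) # corner
})

test_that("select_top_dense keeps everything under the cap, exactly cap above", {
  sim <- simulate_root_mask(60, 60,
    blobs = data.frame(centre_x = 30, centre_y = 30, n_pixels = 100),
    seed = 2
  )
  expect_equal(nrow(select_top_dense(sim$mask, cap = 200)), 100)

  big <- simulate_root_mask(80, 80,
    blobs = data.frame(centre_x = 40, centre_y = 40, n_pixels = 1000),
    seed = 2
  )
  expect_equal(nrow(select_top_dense(big$mask, cap = 200)), 200)
})

test_that("density ties at the cut are broken in row-major order", {
  # isolated pixels on a lattice: every score is 1, so selection is purely
  # positional: the first `cap` pixels in (y, x) order
  px <- matrix(FALSE, 40, 40)
  px[seq(1, 39, by = 2), seq(1, 39, by = 2)] <- TRUE # 400 isolated pixels
  m <- root_mask(px)
  sel <- select_top_dense(m, cap = 200)
  expect_equal(nrow(sel), 200)
  ord <- order(sel[, "y"], sel[, "x"])
  expect_equal(sel[ord, , drop = FALSE], sel[order(sel[, "y"], sel[, "x"]), ])
  # row-major prefix: the selected rows are the topmost lattice rows
  expect_lte(max(sel[, "y"]), 19)
  all_idx <- which(px)
  ys <- (all_idx - 1) %% 40
  xs <- (all_idx - 1) %/% 40
  first200 <- order(ys, xs)[1:200]
  expect_setequal(
    paste(sel[, "x"], sel[, "y"]),
    paste(xs[first200], ys[first200])
  )
})

test_that("partition extractors respect preconditions and recover planted discs", {
  few <- simulate_root_mask(30, 30,
    blobs = data.frame(centre_x = 15, centre_y = 15, n_pixels = 3),
    seed = 1
  )
  xy <- points_from_mask(few$mask)
  km <- extract_partition("kmeans", xy)
  expect_equal(km$status, "insufficient_pixels")
  expect_true(is.na(km$density_points))

  sim <- two_disc_mask(300, 100, seed = 7)
  gx <- points_from_mask(sim$mask)
  gmm <- extract_partition("gmm", gx)
  expect_equal(gmm$status, "ok")
  expect_equal(gmm$density_points, 300)
  expect_lt(
    sqrt((gmm$centre_x - sim$truth$centroid_x[1])^2 +
      (gmm$centre_y - sim$truth$centroid_y[1])^2),
    1
  )
})

test_that("k-means isolates five well-separated discs of graded size", {
  sim <- simulate_root_mask(200, 200,
    blobs = data.frame(
      centre_x = c(40, 160, 40, 160, 100),
      centre_y = c(40, 40, 160, 160, 100),
      n_pixels = c(60, 50, 40, 30, 20)
    ),
    seed = 8
  )
  xy <- points_from_mask(sim$mask)
  km <- extract_partition("kmeans", xy, seed = 1)
  expect_equal(km$density_points, 60)
  expect_lt(abs(km$centre_x - sim$truth$centroid_x[1]), 1)
  expect_lt(abs(km$centre_y - sim$truth$centroid_y[1]), 1)
})

test_that("density extractors flag degenerate inputs", {
  sparse <- root_mask({
    px <- matrix(FALSE, 30, 30)
    px[cbind(c(1, 10, 20, 29, 15), c(1, 10, 20, 29, 25))] <- TRUE
    px
  })
  xy <- points_from_mask(sparse)
  hd <- extract_density("hdbscan", xy)
  expect_true(hd$status %in% c("insufficient_pixels", "no_cluster"))

  lattice <- root_mask({
    px <- matrix(FALSE, 80, 80)
    px[seq(1, 80, by = 8), seq(1, 80, by = 8)] <- TRUE
    px
  })
  db <- extract_density("dbscan", points_from_mask(lattice))
  expect_equal(db$status, "no_cluster")
  expect_true(is.na(db$centre_x))
})

test_that("the custom extractor follows its point-availability rule", {
  single <- root_mask({
    px <- matrix(FALSE, 10, 10)
    px[5, 7] <- TRUE
    px
  })
  tr <- extract_custom(single)
  expect_equal(tr$density_points, 1)
  expect_equal(tr$centre_x, 6) # 0-based column
  expect_equal(tr$centre_y, 4)

  three <- root_mask({
    px <- matrix(FALSE, 60, 60)
    px[cbind(c(5, 55, 30), c(5, 5, 55))] <- TRUE
    px
  })
  tr3 <- extract_custom(three)
  expect_equal(tr3$status, "ok")
  expect_equal(tr3$density_points, 1) # k = 3 distinct points, all singletons

  sim <- simulate_root_mask(200, 200,
    blobs = data.frame(
      centre_x = c(40, 160, 40, 160, 100),
      centre_y = c(40, 40, 160, 160, 100),
      n_pixels = c(60, 50, 40, 30, 20)
    ),
    seed = 9
  )
  trc <- extract_custom(sim$mask, seed = 1)
  expect_equal(trc$density_points, 60)
  expect_lt(abs(trc$centre_x - sim$truth$centroid_x[1]), 1)
  # cross-check against an unweighted k-means oracle on the same points
  sel <- select_top_dense(sim$mask, 200)
  km <- weighted_kmeans(sel, k = 5, nstart = 10, seed = 1)
  oracle_top <- largest_cluster(sel, km$cluster)
  expect_equal(trc$density_points, oracle_top$size)
})

test_that("extract_all always emits the 27-column contract", {
  sim <- five_blob_mask(90, layout_seed = 2)
  row <- extract_all(sim$mask, seed = 1)
  expect_true(all(art_trait_names() %in% names(row)))
  expect_equal(sum(names(row) %in% art_trait_names()), 27)

  empty <- root_mask(matrix(FALSE, 20, 20))
  erow <- extract_all(empty, seed = 1)
  expect_equal(sum(names(erow) %in% art_trait_names()), 27)
  expect_true(all(is.na(unlist(erow[art_trait_names()]))))
  expect_true(all(attr(erow, "statuses") == "insufficient_pixels"))
})

test_that("extraction is deterministic for a fixed seed", {
  sim <- five_blob_mask(100, layout_seed = 3)
  a <- extract_all(sim$mask, seed = 5)
  b <- extract_all(sim$mask, seed = 5)
  expect_identical(a, b)
})

test_that("centroids are translation-equivariant below the subsample cap", {
  base <- simulate_root_mask(160, 160,
    blobs = data.frame(
      centre_x = c(40, 110), centre_y = c(40, 110),
      n_pixels = c(120, 30)
    ),
    seed = 4
  )
  dx <- 13
  dy <- 9
  shifted <- simulate_root_mask(160, 160,
    blobs = data.frame(
      centre_x = c(40 + dx, 110 + dx), centre_y = c(40 + dy, 110 + dy),
      n_pixels = c(120, 30)
    ),
    seed = 4
  )
  # the generator orders pixels by distance-to-centre, so an integer shift
  # produces exactly the translated pixel set
  a <- extract_all(base$mask, seed = 1)
  b <- extract_all(shifted$mask, seed = 1)
  for (alg in setdiff(art_algorithms(), "SLIC")) {
    expect_equal(
      b[[paste0(alg, "_density_points")]],
      a[[paste0(alg, "_density_points")]],
      info = alg
    )
    expect_lt(
      abs(b[[paste0(alg, "_centre_x")]] - a[[paste0(alg, "_centre_x")]] - dx),
      0.5
    )
    expect_lt(
      abs(b[[paste0(alg, "_centre_y")]] - a[[paste0(alg, "_centre_y")]] - dy),
      0.5
    )
  }
  # SLIC's superpixel lattice is anchored to the image, so only approximate
  # equivariance is expected
  expect_lt(abs(b$SLIC_centre_x - a$SLIC_centre_x - dx), 3)
  expect_lt(abs(b$SLIC_centre_y - a$SLIC_centre_y - dy), 3)
})
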