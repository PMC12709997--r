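# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures live in the repository.

# Five well-separated blobs (one dominant), the regime in which all nine
# extractors should agree on the dominant cluster: dominant 70-110 px
# against minor blobs all at or above the density-based minimum cluster
# size of 10, centres ~100 px apart on a 200 x 200 canvas.
five_blob_mask <- function(dominant = 90, layout_seed = 1, jitter = TRUE) {
  withr::with_seed(layout_seed, {
    jit <- if (jitter) runif(10, -8, 8) else rep(0, 10)
  })
  blobs <- data.frame(
    centre_x = c(50, 150, 50, 150, 100) + jit[1:5],
    centre_y = c(50, 50, 150, 150, 100) + jit[6:10],
    n_pixels = c(dominant, 15, 12, 11, 10)
  )
  simulate_root_mask(200, 200, blobs = blobs, seed = layout_seed)
}

# Two solid discs with a wide gap; DBSCAN at eps = 5 must see exactly the
# two connected components.
two_disc_mask <- function(n1 = 300, n2 = 100, seed = 1) {
  simulate_root_mask(120, 200,
    blobs = data.frame(
      centre_x = c(50, 150), centre_y = c(60, 60),
      n_pixels = c(n1, n2)
    ),
    seed = seed
  )
}

# Replicated physiology table: 6 genotypes x 2 treatments, tolerant
# genotypes lose less conductance/water under drought.
physio_fixture <- function(seed = 1, reps = 5) {
  withr::with_seed(seed, {
    genos <- paste0(rep(c("DT_", "DS_"), each = 3), rep(1:3, 2))
    tab <- tidyr::expand_grid(
      genotype = genos,
      treatment = c("control", "drought"),
      rep = seq_len(reps)
    )
    dplyr::mutate(tab,
      tolerant = .data$genotype %in% c("DT_1", "DT_2", "DT_3"),
      drop = (.data$treatment == "drought") * (1 + !.data$tolerant),
      g_s_1 = rnorm(dplyr::n(), 300 - 120 * .data$drop, 12),
      g_s_2 = rnorm(dplyr::n(), 280 - 110 * .data$drop, 12),
      RWC = pmin(100, rnorm(dplyr::n(), 92 - 18 * .data$drop, 2.5)),
      Tiller_no = pmax(0, round(rnorm(dplyr::n(), 10 - 3 * .data$drop, 1)))
    ) |>
      dplyr::select(-"drop")
  })
}

# Labelled table whose trait columns follow the 27-column naming scheme,
# with exactly one algorithm's columns informative.
art_named_table <- function(n_per_class = 60, informative = "FCM", seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    lab <- factor(rep(c("susceptible", "tolerant"), each = n_per_class))
    shift <- ifelse(lab == "tolerant", 1.5, -1.5)
    tab <- purrr::map(art_algorithms(), function(a) {
      cols <- paste0(a, c("_density_points", "_centre_x", "_centre_y"))
      m <- matrix(rnorm(n * 3), n, 3)
      if (a == informative) m <- m + shift
      colnames(m) <- cols
      as.data.frame(m)
    })
  })
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%03d", seq_len(2 * n_per_class)), label = lab),
    dplyr::bind_cols(tab)
  )
}
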