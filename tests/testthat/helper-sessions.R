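# Shared fixtures, built once per test run and cached: the simulator is the
# package's own fixture generator, so nothing is stored on disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A short session for cheap structural tests.
small_session <- function(seed = 3L, duration_s = 300) {
  cached(sprintf("sess_%d_%g", seed, duration_s),
         simulate_session(sim_profile("table3", seed = seed,
                                      duration_s = duration_s)))
}

# The committed full-length profile used by the heavy evaluation tests.
table3_session <- function(seed = 1L) {
  cached(sprintf("table3_%d", seed),
         simulate_session(sim_profile("table3", seed = seed)))
}

table3_features <- function(window_s, seed = 1L) {
  cached(sprintf("fm_%g_%d", window_s, seed), {
    s <- table3_session(seed)
    build_feature_matrix(make_windows(s$trace, s$track,
                                      window_spec(window_s)))
  })
}

# A short session with class 3 boosted enough that even 4-s windows keep
# all three classes: used by grid-level tests that need every class in
# every fold without simulating a full-length session.
rich_session <- function() {
  cached("rich_session",
         simulate_session(sim_profile(
           "table3", seed = 12L, duration_s = 300,
           class_probs = c(0.35, 0.35, 0.30),
           mean_bout_s = c(10, 10, 3))))
}

# A 10000-slot annotation track for label-noise statistics.
new_track_for_noise <- function() {
  cached("noise_track", {
    set.seed(17)
    tk <- data.frame(slot_start = (0:9999) * 0.5,
                     label = sample(1:3, 10000, replace = TRUE))
    class(tk) <- c("annotation_track", "data.frame")
    tk
  })
}

# Three well-separated Gaussian blobs in 5 feature dimensions.
blob_features <- function(n_per_class = c(50, 50, 50), sd = 0.3,
                          seed = 99L) {
  set.seed(seed)
  centers <- rbind(c(0, 0, 0, 0, 0),
                   c(4, 4, 0, 0, 0),
                   c(0, 0, 4, 4, 4))
  rows <- lapply(1:3, function(k) {
    m <- matrix(stats::rnorm(n_per_class[k] * 5, 0, sd),
                n_per_class[k], 5)
    sweep(m, 2, centers[k, ], "+")
  })
  fm <- as.data.frame(do.call(rbind, rows))
  names(fm) <- paste0("f", 1:5)
  fm$label <- rep(1:3, n_per_class)
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

# Independent brute-force oracle for the 31-feature kernel: direct formula
# evaluation, sharing no code with extract_features().
oracle_features <- function(w, bins = 16L) {
  n <- nrow(w)
  out <- numeric(31)
  ax_feats <- function(v) {
    m <- sum(v) / n
    varp <- sum((v - m)^2) / n
    sdp <- sqrt(varp)
    skew <- if (sdp > 0) (sum((v - m)^3) / n) / sdp^3 else 0
    kurt <- if (sdp > 0) (sum((v - m)^4) / n) / varp^2 else 0
    ent <- 0
    if (max(v) > min(v)) {
      cuts <- cut(v, breaks = seq(min(v), max(v), length.out = bins + 1),
                  include.lowest = TRUE)
      p <- as.vector(table(cuts)) / n
      p <- p[p > 0]
      ent <- -sum(p * log2(p))
    }
    c(skew, kurt, m, sdp, varp, min(v), max(v), ent, sum(v^2) / n)
  }
  pcov <- function(a, b) sum((a - mean(a)) * (b - mean(b))) / n
  for (ax in 1:3)
    out[(ax - 1) * 10 + 1:9] <- ax_feats(w[, ax])
  out[10] <- pcov(w[, 2], w[, 3])
  out[20] <- pcov(w[, 1], w[, 3])
  out[30] <- pcov(w[, 1], w[, 2])
  out[31] <- mean(sqrt(w[, 1]^2 + w[, 2]^2 + w[, 3]^2))
  names(out) <- feature_names()
  out
}

# Independent one-vs-rest tally used to cross-check metrics_from_confusion.
oracle_metrics <- function(cm) {
  k <- nrow(cm)
  total <- sum(cm)
  prec <- rec <- f1 <- numeric(k)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    prec[i] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[i] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[i] <- if (prec[i] + rec[i] == 0) 0 else
      2 * prec[i] * rec[i] / (prec[i] + rec[i])
  }
  list(accuracy = sum(diag(cm)) / total, precision = prec, recall = rec,
       f1 = f1, overall_f1 = mean(f1))
}

# Random window generator for property-style loops.
random_window <- function(n = 100, scale = 1) {
  matrix(stats::rnorm(n * 3, sd = scale), n, 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

# Windows whose slots all carry one label (pure-class windows). The
# flanking slot on each side must share the label too: slot labels are
# sample majorities, so a lone boundary slot can hide up to half a slot of
# a neighbouring bout's signal, which only the flank requirement excludes.
pure_window_idx <- function(win, track, cls) {
  slots_per_win <- round(win$spec$window_s / 0.5)
  vapply(seq_along(win$label), function(w) {
    s1 <- round((win$start_s[w] - track$slot_start[1]) / 0.5) + 1
    s_lo <- max(1, s1 - 1)
    s_hi <- min(nrow(track), s1 + slots_per_win)
    all(track$label[s_lo:s_hi] == cls)
  }, logical(1))
}
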