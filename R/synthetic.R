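#' Synthetic multimodal cohort generator
#'
#' Generates cohorts that mimic the structure of utterance-segmented
#' interview corpora: variable-length sessions, subject-level continuous
#' severity labels, and per-modality feature matrices whose informativeness
#' is ordered text > audio > visual.  The planted severity signal has the
#' two temporal structures the model targets:
#'
#' * a **chronic trend** — a latent AR(1) state drifting toward a
#'   severity-dependent mean, expressing severity as a persistent level; and
#' * **intermittent bursts** — short (1-3 utterance) symptomatic episodes
#'   whose onset probability grows with severity, expressing severity as
#'   sparse, jump-connected events.
#'
#' Each utterance's feature vector in modality m is the latent state scaled
#' by that modality's signal strength along a fixed unit direction, plus
#' isotropic Gaussian noise.
#'
#' @name synthetic_data
NULL

## Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic cohort configuration
#'
#' @param n_subjects number of sessions to generate.
#' @param preset named condition: `"default"` (moderate signal),
#'   `"strong"` (strong chronic trend, low noise), `"null"` (all signal
#'   strengths zero: features pure noise, labels independent of features),
#'   `"burst"` (weak trend, severity expressed mainly through burst rate).
#' @param n_utterances length-2 integer range of utterances per session.
#' @param dims named per-modality feature dimensions; the default is a
#'   desk-scale `c(A = 20, V = 32, T = 24)`, and `paper_scale = TRUE`
#'   switches to `c(A = 100, V = 2048, T = 768)`.
#' @param scale label scale, `"PHQ8"` (0-24) or `"BDI"` (0-63).
#' @param snr per-modality signal strengths; default ordering T > A > V.
#' @param trend_strength latent mean at maximum severity (chronic trend).
#' @param ar_phi AR(1) persistence of the latent state, in `[0, 1)`.
#' @param state_sigma innovation s.d. of the latent state.
#' @param burst_base,burst_slope burst onset probability per utterance is
#'   `burst_base + burst_slope * y / y_max`, clipped to `[0, 1]`.
#' @param burst_amp latent offset added during a burst.
#' @param burst_len_max maximum burst length in utterances (lengths are
#'   uniform on `1:burst_len_max`).
#' @param noise_sigma s.d. of the per-coordinate feature noise.
#' @param seed integer seed; generation is fully deterministic given it.
#' @param paper_scale use the full-scale feature dimensions.
#' @return A `mignn_syn_config` list.
#' @export
synthetic_config <- function(n_subjects = 100,
                             preset = c("default", "strong", "null", "burst"),
                             n_utterances = c(20L, 60L),
                             dims = c(A = 20L, V = 32L, T = 24L),
                             scale = c("PHQ8", "BDI"),
                             snr = c(A = 0.7, V = 0.25, T = 1.0),
                             trend_strength = 1.0,
                             ar_phi = 0.8,
                             state_sigma = 0.15,
                             burst_base = 0.05,
                             burst_slope = 0.30,
                             burst_amp = 2.0,
                             burst_len_max = 3L,
                             noise_sigma = 0.6,
                             seed = 1L,
                             paper_scale = FALSE) {
  preset <- match.arg(preset)
  scale <- match.arg(scale)
  if (paper_scale) dims <- c(A = 100L, V = 2048L, T = 768L)
  supplied <- names(match.call())[-1]
  override <- function(arg, value) if (arg %in% supplied) get(arg) else value
  if (preset == "strong") {
    trend_strength <- override("trend_strength", 2.0)
    noise_sigma <- override("noise_sigma", 0.25)
    state_sigma <- override("state_sigma", 0.10)
  } else if (preset == "null") {
    snr <- override("snr", c(A = 0, V = 0, T = 0))
  } else if (preset == "burst") {
    trend_strength <- override("trend_strength", 0.4)
    burst_slope <- override("burst_slope", 0.5)
    burst_base <- override("burst_base", 0.02)
    burst_amp <- override("burst_amp", 2.5)
    noise_sigma <- override("noise_sigma", 0.5)
  }
  stopifnot(
    n_subjects >= 1, length(n_utterances) == 2, n_utterances[1] >= 1,
    n_utterances[2] >= n_utterances[1],
    all(dims >= 1), all(snr >= 0), ar_phi >= 0, ar_phi < 1,
    state_sigma >= 0, noise_sigma >= 0, burst_len_max >= 1,
    trend_strength >= 0, burst_slope >= 0, burst_base >= 0
  )
  structure(
    list(n_subjects = as.integer(n_subjects), preset = preset,
         n_utterances = as.integer(n_utterances), dims = dims, scale = scale,
         snr = snr, trend_strength = trend_strength, ar_phi = ar_phi,
         state_sigma = state_sigma, burst_base = burst_base,
         burst_slope = burst_slope, burst_amp = burst_amp,
         burst_len_max = as.integer(burst_len_max),
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "mignn_syn_config")
}

#' Generate a synthetic cohort with ground truth
#'
#' @param cfg a [synthetic_config()].
#' @return A list with elements `cohort` (an `mignn_cohort`) and `truth`
#'   (per session: the severity `y`, the latent state trajectory `latent`
#'   including burst offsets, and the logical `burst_mask`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "mignn_syn_config"))
  y_max <- SCALE_RANGE[[cfg$scale]][2]
  mods <- names(cfg$dims)
  ## fixed unit direction per modality: a population parameter shared by
  ## every cohort with the same dimensions (train/dev/test must live in the
  ## same feature subspace), hence seeded by the dimension, not the cohort
  dirs <- lapply(mods, function(m) {
    with_seed(104729L + cfg$dims[[m]], {
      v <- rnorm(cfg$dims[[m]])
      v / sqrt(sum(v^2))
    })
  })
  names(dirs) <- mods
  with_seed(cfg$seed, {
    samples <- vector("list", cfg$n_subjects)
    truth <- vector("list", cfg$n_subjects)
    for (s in seq_len(cfg$n_subjects)) {
      y <- runif(1, 0, y_max)
      n <- sample(cfg$n_utterances[1]:cfg$n_utterances[2], 1)
      m_lat <- cfg$trend_strength * y / y_max
      st <- numeric(n)
      st[1] <- m_lat + rnorm(1, 0, cfg$state_sigma /
                                  max(sqrt(1 - cfg$ar_phi^2), 1e-12))
      if (n > 1) {
        eps <- rnorm(n - 1, 0, cfg$state_sigma)
        for (i in 2:n)
          st[i] <- m_lat + cfg$ar_phi * (st[i - 1] - m_lat) + eps[i - 1]
      }
      p_burst <- min(max(cfg$burst_base + cfg$burst_slope * y / y_max, 0), 1)
      mask <- logical(n)
      i <- 1L
      while (i <= n) {
        if (runif(1) < p_burst) {
          len <- sample.int(cfg$burst_len_max, 1)
          mask[i:min(n, i + len - 1L)] <- TRUE
          i <- i + len
        } else i <- i + 1L
      }
      latent <- st + cfg$burst_amp * mask
      feats <- lapply(mods, function(m) {
        signal <- (cfg$snr[[m]] * latent) %o% dirs[[m]]
        signal + matrix(rnorm(n * cfg$dims[[m]], 0, cfg$noise_sigma),
                        n, cfg$dims[[m]])
      })
      names(feats) <- mods
      sid <- sprintf("syn%04d", s)
      samples[[s]] <- session_sample(sid, feats, y, cfg$scale)
      truth[[s]] <- list(session_id = sid, y = y, latent = latent,
                         burst_mask = mask)
    }
    list(cohort = as_cohort(samples), truth = truth)
  })
}

#' Generator-inversion severity estimate (performance ceiling)
#'
#' Closed-form flat-prior posterior mean of the severity given the latent
#' state trajectory and burst mask — i.e. the generator inverted with its
#' own parameters.  Two independent estimators are combined by precision
#' weighting: the AR(1)-innovation estimate of the chronic trend level, and
#' the binomial estimate of the burst onset rate.  A trained model observes
#' only the noisy features, so its cohort CCC cannot meaningfully exceed the
#' oracle's.
#'
#' @param latent numeric latent state trajectory (with burst offsets).
#' @param burst_mask logical burst indicator per utterance.
#' @param cfg the [synthetic_config()] used for generation.
#' @return Estimated severity, clipped to the scale range.
#' @export
oracle_score <- function(latent, burst_mask, cfg) {
  stopifnot(inherits(cfg, "mignn_syn_config"))
  n <- length(latent)
  if (length(burst_mask) != n)
    stopf("burst mask length %d does not match %d latent states",
          length(burst_mask), n)
  y_max <- SCALE_RANGE[[cfg$scale]][2]
  phi <- cfg$ar_phi
  s0 <- latent - cfg$burst_amp * burst_mask

  est <- numeric(0); prec <- numeric(0)
  if (cfg$trend_strength > 0) {
    ## stationary start + innovations: both unbiased for the latent mean
    parts_m <- s0[1]
    parts_w <- (1 - phi^2) / max(cfg$state_sigma^2, 1e-24)
    if (n > 1) {
      d <- s0[-1] - phi * s0[-n]
      parts_m <- c(parts_m, mean(d) / (1 - phi))
      parts_w <- c(parts_w,
                   (n - 1) * (1 - phi)^2 / max(cfg$state_sigma^2, 1e-24))
    }
    m_hat <- sum(parts_m * parts_w) / sum(parts_w)
    y_trend <- m_hat * y_max / cfg$trend_strength
    if (cfg$state_sigma == 0) return(min(max(y_trend, 0), y_max))
    var_m <- 1 / sum(parts_w)
    est <- c(est, y_trend)
    prec <- c(prec, 1 / (var_m * (y_max / cfg$trend_strength)^2))
  }
  if (cfg$burst_slope > 0) {
    runs <- rle(burst_mask)
    n_starts <- sum(runs$values)
    trials <- n - sum(burst_mask) + n_starts
    p_hat <- n_starts / max(trials, 1)
    y_burst <- (p_hat - cfg$burst_base) / cfg$burst_slope * y_max
    p_t <- min(max(p_hat, 0.5 / max(trials, 1)), 1 - 0.5 / max(trials, 1))
    var_b <- p_t * (1 - p_t) / max(trials, 1) * (y_max / cfg$burst_slope)^2
    est <- c(est, y_burst)
    prec <- c(prec, 1 / var_b)
  }
  if (!length(est)) return(y_max / 2)
  min(max(sum(est * prec) / sum(prec), 0), y_max)
}

#' Oracle scores for a generated cohort
#'
#' @param gen output of [generate_cohort()].
#' @param cfg the generating [synthetic_config()].
#' @return Numeric vector of oracle severity estimates, one per session.
#' @export
oracle_scores <- function(gen, cfg) {
  vapply(gen$truth, function(tr) oracle_score(tr$latent, tr$burst_mask, cfg),
         numeric(1))
}
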