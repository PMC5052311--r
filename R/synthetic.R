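#' Parameters of the synthetic breath-cohort generator
#'
#' The generator emulates the statistical structure of a two-class e-nose
#' case-control study: head-and-neck squamous cell carcinoma (HNSCC) versus
#' primary lung carcinoma, with an imbalanced cohort (52 vs 32 by default),
#' five measurement devices, and smoking/fasting confounders. Each patient
#' carries a latent VOC abundance vector whose class means differ by
#' `delta` along a fixed direction; the forward model of
#' [simulate_measurement()] maps it to a 32x36x3 conductivity tensor.
#'
#' @param n_hnscc,n_lung Patients per class (defaults 52 and 32).
#' @param k_voc Latent VOC dimension (default 8).
#' @param delta Class-separation magnitude in latent units (default 2);
#'   `delta = 0` gives a null cohort with no class signal.
#' @param sigma_noise Scale of the multiplicative log-normal sensor noise
#'   (default 0.05).
#' @param smoking_effect,fasting_effect Latent shifts added for current
#'   smokers and for patients measured in a non-fasted state, along fixed
#'   directions orthogonal to the class direction (defaults 0.5, 0.3).
#' @param n_devices Number of devices (default 5).
#' @param device_gain_sd Standard deviation of per-device, per-sensor
#'   multiplicative gains around 1 (default 0.02).
#' @param drift_tau Warm-up time constant of the cycle-to-cycle drift, in
#'   cycles (default 6).
#' @param seed Master seed; fixes covariates, latent draws, response kernels
#'   and device gains.
#' @param allow_empty Allow a class with zero patients (such a cohort cannot
#'   be used for training).
#' @return A `generator_params` list.
#' @export
generator_params <- function(n_hnscc = 52, n_lung = 32, k_voc = 8,
                             delta = 2.0, sigma_noise = 0.05,
                             smoking_effect = 0.5, fasting_effect = 0.3,
                             n_devices = 5, device_gain_sd = 0.02,
                             drift_tau = 6.0, seed = 1,
                             allow_empty = FALSE) {
  p <- list(n_hnscc = as.integer(n_hnscc), n_lung = as.integer(n_lung),
            k_voc = as.integer(k_voc), delta = delta,
            sigma_noise = sigma_noise, smoking_effect = smoking_effect,
            fasting_effect = fasting_effect, n_devices = as.integer(n_devices),
            device_gain_sd = device_gain_sd, drift_tau = drift_tau,
            seed = as.integer(seed), allow_empty = isTRUE(allow_empty))
  stopifnot(p$n_hnscc >= 0, p$n_lung >= 0, p$k_voc >= 1, p$delta >= 0,
            p$sigma_noise >= 0, p$device_gain_sd >= 0, p$drift_tau > 0,
            p$n_devices >= 1)
  structure(p, class = "generator_params")
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 9973) %% 2147483629 + 1)
}

#' Smooth per-sensor baseline over the temperature ladder
#'
#' Fixed positive response of each clean sensor across the 32-step
#' 260-340 degC heating/cooling ladder; a Gaussian hump with a
#' sensor-specific centre on top of a constant offset. Deterministic (no
#' seed dependence), so the forward model's closed form can be checked
#' exactly.
#'
#' @return 32 x 3 matrix `B[t, s]` of baseline conductivities.
#' @export
sensor_baseline <- function() {
  t <- seq_len(32)
  centres <- c(8, 16, 25)
  sapply(seq_len(3), function(s) {
    0.8 + 0.6 * exp(-0.5 * ((t - centres[s]) / 9)^2)
  })
}

# Gaussian-bump response kernels a[t, s, k] and the fixed latent directions
# (class u, smoking w_s, fasting w_f, mutually orthogonalised); both are
# frozen functions of the master seed so the class signal lives only in the
# per-patient latent vectors.
generator_structure <- function(p) {
  withr::with_seed(derive_seed(p$seed, 1), {
    a <- array(0, c(32, 3, p$k_voc))
    t <- seq_len(32)
    for (s in 1:3) {
      for (k in seq_len(p$k_voc)) {
        centre <- stats::runif(1, 1, 32)
        width <- stats::runif(1, 2, 6)
        amp <- stats::rnorm(1, 0, 0.05)
        a[, s, k] <- amp * exp(-0.5 * ((t - centre) / width)^2)
      }
    }
    unit <- function(v) v / sqrt(sum(v^2))
    u <- unit(stats::rnorm(p$k_voc))
    orth <- function(v, basis) {
      for (b in basis) v <- v - sum(v * b) * b
      unit(v)
    }
    w_s <- orth(stats::rnorm(p$k_voc), list(u))
    w_f <- orth(stats::rnorm(p$k_voc), list(u, w_s))
    gains <- matrix(stats::rnorm(p$n_devices * 3, 1, p$device_gain_sd),
                    p$n_devices, 3)
    list(kernels = a, u = u, w_smoking = w_s, w_fasting = w_f, gains = gains)
  })
}

#' Simulate one e-nose measurement from a latent VOC profile
#'
#' Forward model of the temperature-cycled metal-oxide sensor response:
#' \deqn{x[t,c,s] = B_s(t)\,\big(1 + \sum_k a_{s,k}(t)\, v_k\big)\,
#'   \big(1 - 0.2\, e^{-c/\tau}\big)\, g_{d,s}\, \varepsilon_{tcs}}
#' where \eqn{B_s(t)} is the fixed smooth baseline ([sensor_baseline()]),
#' \eqn{a_{s,k}(t)} are Gaussian-bump response kernels frozen by the master
#' seed, the exponential term is a warm-up drift over cycles (depth 0.2,
#' time constant `drift_tau`), \eqn{g_{d,s}} is the device gain and
#' \eqn{\varepsilon} is i.i.d. log-normal noise with log-scale
#' `sigma_noise`. Output is clipped below at `1e-6` to keep conductivities
#' positive.
#'
#' @param v Latent VOC abundance vector of length `k_voc`.
#' @param device Device index in `1..n_devices`.
#' @param p A [generator_params()].
#' @param seed Seed for the measurement noise.
#' @return A [breath_tensor()].
#' @export
simulate_measurement <- function(v, device, p, seed = 1) {
  stopifnot(length(v) == p$k_voc, all(is.finite(v)),
            device >= 1, device <= p$n_devices)
  s <- generator_structure(p)
  resp <- sensor_baseline() *
    (1 + apply(sweep(s$kernels, 3, v, `*`), c(1, 2), sum)) # 32 x 3
  warm <- 1 - 0.2 * exp(-seq_len(36) / p$drift_tau)
  x <- array(0, tensor_dims())
  for (sn in 1:3) {
    x[, , sn] <- outer(resp[, sn], warm) * s$gains[device, sn]
  }
  eps <- withr::with_seed(derive_seed(seed, 2), {
    if (p$sigma_noise > 0) {
      array(exp(stats::rnorm(length(x), 0, p$sigma_noise)), dim(x))
    } else {
      array(1, dim(x))
    }
  })
  breath_tensor(pmax(x * eps, 1e-6))
}

#' Generate a synthetic breath cohort
#'
#' Draws labels, clinical covariates, latent VOC profiles and measurements
#' for a full case-control cohort. Covariate margins follow the emulated
#' study's baseline table: current smoking ~62 % in HNSCC vs ~41 % in lung;
#' fasting status mostly non-fasted in lung (30/32 ate within 4 h) and mixed
#' with unknowns in HNSCC (28 yes / 12 no / 12 unknown out of 52); devices
#' uniform; age ~ N(63, 10) / N(65, 10); sex, tumor stage, histology and
#' subsite at the table's observed proportions. Latent profiles are
#' `v = mu_class + z` with `z` standard normal, the class means `delta`
#' apart along a fixed unit direction, plus smoking/fasting shifts (applied
#' for known non-fasted patients only; unknown status gets no shift).
#' Identical parameters (including `seed`) reproduce the cohort exactly.
#'
#' @param p A [generator_params()].
#' @return A [breath_dataset()].
#' @export
sample_cohort <- function(p = generator_params()) {
  stopifnot(inherits(p, "generator_params"))
  if ((p$n_hnscc == 0 || p$n_lung == 0) && !p$allow_empty) {
    stop("both classes need at least one patient for downstream training ",
         "(pass allow_empty = TRUE to override)", call. = FALSE)
  }
  s <- generator_structure(p)
  n <- p$n_hnscc + p$n_lung
  labels <- rep(c("HNSCC", "LUNG"), c(p$n_hnscc, p$n_lung))
  serials <- if (p$n_devices == 5) c("2599", "3092", "3154", "3629", "3798")
             else sprintf("D%02d", seq_len(p$n_devices))
  stage_prob <- list(
    HNSCC = c(I = 16, II = 10, III = 5, IV = 19, missing = 2) / 52,
    LUNG = c(I = 4, II = 1, III = 10, IV = 16, missing = 1) / 32)
  histo_prob <- list(
    HNSCC = c(squamous = 1),
    LUNG = c(squamous = 5, adenocarcinoma = 18, small_cell = 3, other = 6) / 32)
  subsite_prob <- c(oral_cavity = 15, oropharynx = 13, nasopharynx = 2,
                    hypopharynx = 3, larynx = 19) / 52
  recs <- withr::with_seed(derive_seed(p$seed, 3), {
    lapply(seq_len(n), function(i) {
      lab <- labels[i]
      hn <- lab == "HNSCC"
      smoking <- stats::runif(1) < if (hn) 32 / 52 else 13 / 32
      fasted <- if (hn) {
        sample(c(FALSE, TRUE, NA), 1, prob = c(28, 12, 12) / 52)
      } else {
        sample(c(FALSE, TRUE), 1, prob = c(30, 2) / 32)
      }
      mu <- (if (hn) p$delta / 2 else -p$delta / 2) * s$u
      v <- mu + stats::rnorm(p$k_voc) +
        (if (smoking) p$smoking_effect * s$w_smoking else 0) +
        (if (isFALSE(fasted)) p$fasting_effect * s$w_fasting else 0)
      device <- sample.int(p$n_devices, 1)
      meas_seed <- sample.int(2147483600L, 1)
      patient_record(
        patient_id = sprintf("P%03d", i), label = lab,
        tensor = simulate_measurement(v, device, p, seed = meas_seed),
        age = round(stats::rnorm(1, if (hn) 63 else 65, 10)),
        sex = if (stats::runif(1) < (if (hn) 43 / 52 else 20 / 32)) "M" else "F",
        smoking = smoking, fasted = fasted,
        device_serial = serials[device],
        tumor_stage = sample(names(stage_prob[[lab]]), 1,
                             prob = stage_prob[[lab]]),
        histology = sample(names(histo_prob[[lab]]), 1,
                           prob = histo_prob[[lab]]),
        subsite = if (hn) sample(names(subsite_prob), 1, prob = subsite_prob)
                  else NA_character_)
    })
  })
  breath_dataset(recs, sprintf(
    "synthetic e-nose cohort: n=%d+%d, delta=%g, sigma=%g, seed=%d",
    p$n_hnscc, p$n_lung, p$delta, p$sigma_noise, p$seed))
}
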