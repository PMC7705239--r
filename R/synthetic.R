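# Surrogate Bonn-like EEG generator: class-dependent spectral structure on a
# 1/f background, with one separability knob scaling every class contrast.

#' Specification for the surrogate EEG generator
#'
#' Defaults emulate the Bonn corpus layout: five sets (A, B healthy surface;
#' C, D interictal; E ictal) of 100 records, 4097 samples at 173.61 Hz. The
#' generative recipe is standard EEG phenomenology, not a fit to the real
#' data: a 1/f-shaped Gaussian background everywhere; a ~10 Hz alpha rhythm
#' on A and B (stronger with eyes closed, B); sparse interictal transient
#' spikes on C and D; and a high-amplitude ~3 Hz spike-and-wave train on E.
#' Every set-specific component's amplitude is multiplied by `separability`,
#' so `separability = 0` collapses all five sets onto the identical 1/f
#' distribution, and large values make the classes trivially separable.
#'
#' @param n_records_per_set Records per set (default 100).
#' @param record_length Samples per record (default 4097).
#' @param sampling_rate_hz Sampling rate (default 173.61).
#' @param seed Integer seed; drives a per-set, per-record seed sequence so
#'   any subset regenerates identically regardless of order.
#' @param separability Non-negative contrast knob (default 1 = moderate).
#' @param noise_sd Standard deviation of the 1/f background (default 1).
#' @param clip Absolute amplitude bound applied last (default `100 *
#'   noise_sd`).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_records_per_set = 100L, record_length = 4097L,
                           sampling_rate_hz = 173.61, seed = 1L,
                           separability = 1, noise_sd = 1,
                           clip = 100 * noise_sd) {
  if (n_records_per_set < 1L || record_length < 1L)
    stop("counts must be positive")
  if (separability < 0) stop("separability must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  structure(
    list(n_records_per_set = as.integer(n_records_per_set),
         record_length = as.integer(record_length),
         sampling_rate_hz = sampling_rate_hz, seed = as.integer(seed),
         separability = separability, noise_sd = noise_sd, clip = clip),
    class = "synthetic_spec")
}

# Deterministic per-record seed below 2^31, mixed from (seed, set, record).
record_seed <- function(seed, set_idx, rec_idx) {
  as.integer((as.double(seed %% 100003L) * 7919 + set_idx * 1299709 +
                rec_idx * 104729) %% 2147483629)
}

# Gaussian noise with ~1/f power spectrum (amplitude ~ f^(-1/2)), rescaled
# to standard deviation `sd`. Frequencies below f_floor share the floor's
# gain so the DC region does not blow up.
one_over_f_noise <- function(n, fs, sd = 1, f_floor = 0.5) {
  white <- rnorm(n)
  spec <- fft(white)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                      # two-sided spectrum symmetry
  gain <- 1 / sqrt(pmax(f, f_floor))
  gain[1] <- 0                              # remove DC
  x <- Re(fft(spec * gain, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x * sd / s else x
}

# One surrogate record for a given set.
synth_record_samples <- function(spec, set_id, rec_idx) {
  set.seed(record_seed(spec$seed, match(set_id, SET_IDS), rec_idx))
  n <- spec$record_length
  fs <- spec$sampling_rate_hz
  tt <- (seq_len(n) - 1) / fs
  sep <- spec$separability
  x <- one_over_f_noise(n, fs, sd = spec$noise_sd)
  amp <- sep * spec$noise_sd
  if (set_id %in% c("A", "B")) {
    # alpha rhythm, stronger with eyes closed (B)
    f0 <- 10 + runif(1, -0.5, 0.5)
    a <- if (set_id == "A") 0.8 else 1.4
    x <- x + a * amp * sin(2 * pi * f0 * tt + runif(1, 0, 2 * pi))
  } else if (set_id %in% c("C", "D")) {
    # sparse interictal transients; D (epileptogenic zone) denser/larger
    rate_hz <- if (set_id == "C") 0.3 else 0.5
    a <- if (set_id == "C") 2.0 else 2.5
    n_spk <- rpois(1, rate_hz * n / fs)
    if (n_spk > 0) {
      centers <- sort(sample.int(n, n_spk))
      half <- round(0.15 * fs)
      for (ctr in centers) {
        lo <- max(1L, ctr - half); hi <- min(n, ctr + half)
        win <- lo:hi
        tw <- (win - ctr) / fs
        w_s <- 0.04
        pulse <- (tw / w_s) * exp(0.5 - 0.5 * (tw / w_s)^2)
        x[win] <- x[win] + a * amp * pulse * sample(c(-1, 1), 1)
      }
    }
  } else if (set_id == "E") {
    # ictal spike-and-wave: harmonic-rich ~3 Hz train with slow envelope
    f0 <- 3 + runif(1, -0.3, 0.3)
    ph <- runif(1, 0, 2 * pi)
    wave <- sin(2 * pi * f0 * tt + ph) + 0.6 * sin(4 * pi * f0 * tt + 2 * ph) +
      0.3 * sin(6 * pi * f0 * tt + 3 * ph)
    env <- 1 + 0.3 * sin(2 * pi * runif(1, 0.1, 0.3) * tt + runif(1, 0, 2 * pi))
    x <- x + 2.0 * amp * wave * env
  }
  pmin(pmax(x, -spec$clip), spec$clip)
}

#' Generate a surrogate Bonn-like corpus
#'
#' Produces five sets of records per the generator specification;
#' deterministic per seed, and any record is reproducible independently of
#' generation order. See [synthetic_spec()] for the generative model.
#'
#' @param spec A [synthetic_spec()] (default: the standard corpus layout).
#' @param sets Which sets to generate (default all five).
#' @return List of [eeg_record()] objects, `length(sets) *
#'   n_records_per_set` long.
#' @export
generate_bonn_like <- function(spec = synthetic_spec(), sets = SET_IDS) {
  stopifnot(inherits(spec, "synthetic_spec"))
  records <- vector("list", length(sets) * spec$n_records_per_set)
  i <- 0L
  for (s in sets) {
    for (r in seq_len(spec$n_records_per_set) - 1L) {
      i <- i + 1L
      records[[i]] <- eeg_record(synth_record_samples(spec, s, r), s, r,
                                 spec$sampling_rate_hz)
    }
  }
  records
}

#' Write records to disk in a reader-compatible layout
#'
#' `bonn_ascii` writes one subdirectory per set with one ASCII file per
#' record (one sample per line, 17 significant digits so read-back is
#' bit-exact). `uci_csv` segments each record into 23 chunks and writes a
#' single CSV with an ID column, sample columns X1..XL and a trailing label
#' column `y` in the UCI coding (E=1 .. A=5).
#'
#' @param records List of [eeg_record()] objects.
#' @param out_dir Output directory (created if needed).
#' @param layout `"bonn_ascii"` or `"uci_csv"`.
#' @param n_chunks Chunks per record for the CSV layout (default 23).
#' @return Invisibly, the path written (directory or CSV file).
#' @export
write_synthetic <- function(records, out_dir,
                            layout = c("bonn_ascii", "uci_csv"),
                            n_chunks = 23L) {
  layout <- match.arg(layout)
  if (length(records) == 0L) stop("no records to write")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create ", out_dir)
  if (layout == "bonn_ascii") {
    for (rec in records) {
      sub <- file.path(out_dir, rec$set_id)
      dir.create(sub, showWarnings = FALSE)
      f <- file.path(sub, sprintf("%s%03d.txt", rec$set_id,
                                  rec$record_index))
      writeLines(sprintf("%.17g", rec$samples), f)
    }
    return(invisible(out_dir))
  }
  tab <- segment_records(records, n_chunks)
  ids <- sprintf("S.%s.%d.%d", tab$provenance$set_id,
                 tab$provenance$record_index, tab$provenance$chunk_index)
  y <- match(tab$provenance$set_id, UCI_LABEL_TO_SET)  # E=1 .. A=5
  df <- data.frame(id = ids,
                   matrix(sprintf("%.17g", tab$segments),
                          nrow = nrow(tab$segments)),
                   y = y, check.names = FALSE)
  names(df)[2:(1 + tab$segment_length)] <- paste0("X", seq_len(tab$segment_length))
  f <- file.path(out_dir, "segments.csv")
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  invisible(f)
}
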