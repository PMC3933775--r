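#' Describe a block design of auditory stimuli
#'
#' A stimulus design lists the sound exemplars of each category and how the
#' session is organised into blocks. The default arguments encode the coma
#' AEP protocol this package models: four blocks, each presenting 20 living
#' sounds (12 animal and 8 human vocalization exemplars) and 20 man-made
#' sounds twice, 500 ms sounds at 22,500 Hz, with an inter-stimulus interval
#' of 2 +/- 0.2 s.
#'
#' @param n_blocks Number of blocks (>= 1).
#' @param living_exemplars Data frame with columns `name` and `subclass`
#'   (`"animal"` or `"human"`), one row per living-sound exemplar.
#' @param manmade_exemplars Character vector of man-made exemplar names.
#' @param repeats_per_block Times each exemplar is presented per block.
#' @param isi_mean Mean inter-stimulus interval, seconds (sound offset to
#'   next sound onset).
#' @param isi_jitter Uniform half-width of the ISI jitter, seconds; must be
#'   smaller than `isi_mean`.
#' @param sound_duration Sound duration, seconds.
#' @param audio_rate Audio sampling rate, Hz.
#'
#' @return An object of class `stimulus_design`.
#' @seealso [make_schedule()]
#' @export
stimulus_design <- function(n_blocks = 4,
                            living_exemplars = default_living_exemplars(),
                            manmade_exemplars = default_manmade_exemplars(),
                            repeats_per_block = 2,
                            isi_mean = 2,
                            isi_jitter = 0.2,
                            sound_duration = 0.5,
                            audio_rate = 22500) {
  living_exemplars <- as.data.frame(living_exemplars)
  stopifnot(
    n_blocks >= 1, repeats_per_block >= 1,
    isi_mean > 0, isi_jitter >= 0, sound_duration > 0, audio_rate > 0,
    all(c("name", "subclass") %in% names(living_exemplars))
  )
  if (isi_jitter >= isi_mean) {
    stop("`isi_jitter` must be smaller than `isi_mean`", call. = FALSE)
  }
  if (nrow(living_exemplars) == 0 || length(manmade_exemplars) == 0) {
    stop("invalid design: exemplar lists must be non-empty", call. = FALSE)
  }
  if (!all(living_exemplars$subclass %in% c("animal", "human"))) {
    stop("living subclasses must be \"animal\" or \"human\"", call. = FALSE)
  }
  if (anyDuplicated(c(living_exemplars$name, manmade_exemplars))) {
    stop("exemplar names must be unique", call. = FALSE)
  }
  structure(
    list(
      n_blocks = as.integer(n_blocks),
      living_exemplars = living_exemplars,
      manmade_exemplars = as.character(manmade_exemplars),
      repeats_per_block = as.integer(repeats_per_block),
      isi_mean = isi_mean,
      isi_jitter = isi_jitter,
      sound_duration = sound_duration,
      audio_rate = audio_rate
    ),
    class = "stimulus_design"
  )
}

default_living_exemplars <- function() {
  data.frame(
    name = c("sheep", "rooster", "pig", "owl", "frog", "donkey", "dog",
             "crow", "chicken", "cow", "cat", "birds",
             "whistling", "sneezing", "screaming", "laughing", "gargling",
             "coughing", "throat_clearing", "crying"),
    subclass = rep(c("animal", "human"), c(12L, 8L)),
    stringsAsFactors = FALSE
  )
}

default_manmade_exemplars <- function() {
  c("accordion", "bicycle_bell", "car_horn", "cash_register", "church_bell",
    "cuckoo_clock", "doorbell", "door_closing", "flute", "glass_shattering",
    "guitar", "harmonica", "harp", "organ", "piano", "police_siren",
    "saxophone", "telephone", "trumpet", "violin")
}

#' @export
print.stimulus_design <- function(x, ...) {
  n_live <- nrow(x$living_exemplars)
  cat(sprintf(
    "stimulus_design: %d block(s), %d living (%d animal + %d human) + %d man-made exemplars x%d, ISI %.2g +/- %.2g s\n",
    x$n_blocks, n_live,
    sum(x$living_exemplars$subclass == "animal"),
    sum(x$living_exemplars$subclass == "human"),
    length(x$manmade_exemplars), x$repeats_per_block,
    x$isi_mean, x$isi_jitter
  ))
  invisible(x)
}

#' Generate a pseudo-random session schedule
#'
#' Expands a [stimulus_design()] into an ordered event table. Within each
#' block, the multiset of exemplars (each repeated `repeats_per_block` times)
#' is shuffled uniformly at random; onsets accumulate sound duration plus an
#' inter-stimulus interval drawn uniformly from
#' `isi_mean +/- isi_jitter`. The result is deterministic given `seed`.
#'
#' @param design A [stimulus_design()].
#' @param eeg_rate EEG sampling rate, Hz; onsets are expressed in EEG samples.
#' @param seed Integer seed controlling shuffling and ISI jitter.
#' @return A data frame of class `session_schedule` with columns `block`,
#'   `onset_sample` (1-based EEG sample of sound onset), `category`
#'   (`"animal"`, `"human"` or `"manmade"`) and `exemplar`, plus attributes
#'   `eeg_rate`, `seed` and `design`.
#' @examples
#' sched <- make_schedule(stimulus_design(), seed = 1)
#' table(sched$category)
#' @export
make_schedule <- function(design, eeg_rate = 1024, seed) {
  stopifnot(inherits(design, "stimulus_design"), eeg_rate > 0)
  categories <- c(
    design$living_exemplars$subclass,
    rep("manmade", length(design$manmade_exemplars))
  )
  names(categories) <- c(design$living_exemplars$name, design$manmade_exemplars)

  events <- with_seed(seed, {
    out <- vector("list", design$n_blocks)
    for (b in seq_len(design$n_blocks)) {
      pool <- rep(names(categories), each = design$repeats_per_block)
      pool <- sample(pool)
      isi <- runif(length(pool), design$isi_mean - design$isi_jitter,
                   design$isi_mean + design$isi_jitter)
      # onset-to-onset gap = sound duration + ISI; first onset after one ISI
      onsets_s <- cumsum(c(isi[1], design$sound_duration + isi[-1]))
      out[[b]] <- data.frame(
        block = b,
        onset_s = onsets_s,
        category = unname(categories[pool]),
        exemplar = pool,
        stringsAsFactors = FALSE
      )
    }
    out
  })

  # blocks are laid end to end with one mean ISI of silence between them
  block_dur <- vapply(events, function(e) {
    max(e$onset_s) + design$sound_duration + design$isi_mean
  }, numeric(1))
  offset <- cumsum(c(0, head(block_dur, -1)))
  for (b in seq_along(events)) events[[b]]$onset_s <- events[[b]]$onset_s + offset[b]
  sched <- do.call(rbind, events)
  sched$onset_sample <- as.integer(round_half_away(sched$onset_s * eeg_rate)) + 1L
  sched <- sched[, c("block", "onset_sample", "category", "exemplar")]
  rownames(sched) <- NULL
  structure(sched,
            eeg_rate = eeg_rate, seed = seed, design = design,
            class = c("session_schedule", "data.frame"))
}

#' Write or read a session schedule as TSV
#'
#' The table keeps the four event columns (`block`, `onset_sample`,
#' `category`, `exemplar`); the EEG rate is stored in a `# eeg_rate:` header
#' comment line.
#'
#' @param schedule A `session_schedule`.
#' @param path File path.
#' @return `read_schedule()` returns a `session_schedule`;
#'   `write_schedule()` returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# eeg_rate: %.10g", attr(schedule, "eeg_rate") %||% NA_real_), con)
  write.table(as.data.frame(schedule), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  first <- readLines(path, n = 1L)
  rate <- if (startsWith(first, "# eeg_rate:")) {
    as.numeric(sub("# eeg_rate:", "", first, fixed = TRUE))
  } else NA_real_
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(df, eeg_rate = rate, class = c("session_schedule", "data.frame"))
}
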