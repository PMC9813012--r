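#' The default chunk set: "apple", "grape", "banana"
#'
#' Each chunk pairs a letter sequence on the text-tone channel with a
#' procedurally drawn image on the image channel.
#'
#' @param stim [stim_params()] controlling image size.
#' @return A named list of chunk specs, each with fields `name`, `letters`
#'   and `image`.
#' @export
default_chunks <- function(stim = stim_params()) {
  specs <- list(
    apple  = c("a", "p", "p", "l", "e"),
    grape  = c("g", "r", "a", "p", "e"),
    banana = c("b", "a", "n", "a", "n", "a")
  )
  lapply(names(specs), function(nm) {
    chunk_spec(nm, specs[[nm]], chunk_image(nm, size = stim$image_size),
               alphabet = stim$alphabet)
  }) |> stats::setNames(names(specs))
}

#' Construct and validate a chunk specification
#'
#' @param name chunk label.
#' @param letters ordered character vector of letters.
#' @param image `size x size x 3` RGB array with values in \[0, 1\].
#' @param alphabet admissible letters.
#' @return A list of class `rc_chunk`.
#' @export
chunk_spec <- function(name, letters, image, alphabet = base::letters) {
  if (length(letters) == 0) stop("chunk '", name, "' has no letters")
  bad <- setdiff(letters, alphabet)
  if (length(bad) > 0)
    stop("chunk '", name, "' uses letters outside the alphabet: ",
         paste(bad, collapse = ", "))
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("chunk image must be an RGB array (h x w x 3)")
  structure(list(name = name, letters = letters, image = image),
            class = "rc_chunk")
}

#' Procedural stand-in image for a named chunk
#'
#' Draws a distinct colored shape per chunk on a mid-gray background: a red
#' disk ("apple"), a cluster of violet disks ("grape"), a yellow crescent
#' ("banana"). Only inter-chunk discriminability matters for the model, not
#' photographic realism. The mid-gray (0.5) background matters: like the
#' photographs these images stand in for, they are full-field, with the same
#' mean intensity as the Gaussian-noise images used as random separators, so
#' chunks are distinguished by repeatable structure rather than by a gross
#' brightness cue.
#'
#' @param name one of `"apple"`, `"grape"`, `"banana"`.
#' @param size square image edge in pixels.
#' @param noise_sd optional additive Gaussian pixel noise (clipped to
#'   \[0, 1\]); draws from the current RNG stream.
#' @return A `size x size x 3` array with values in \[0, 1\].
#' @export
chunk_image <- function(name, size = 60, noise_sd = 0) {
  img <- array(0.5, dim = c(size, size, 3))
  cx <- (size + 1) / 2
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)  # column index
  ys <- matrix(seq_len(size), size, size)                # row index
  disk <- function(x0, y0, rad) (xs - x0)^2 + (ys - y0)^2 <= rad^2
  paint <- function(mask, rgb) {
    for (c in 1:3) {
      ch <- img[, , c]
      ch[mask] <- rgb[c]
      img[, , c] <<- ch
    }
  }
  switch(name,
    apple = {
      paint(disk(cx, cx + size * 0.05, size * 0.32), c(0.90, 0.10, 0.10))
      paint(ys < cx - size * 0.25 & abs(xs - cx) < size * 0.04 &
              ys > cx - size * 0.42, c(0.35, 0.22, 0.05))  # stem
    },
    grape = {
      for (row in 0:2) {
        n <- 3 - row
        for (j in seq_len(n)) {
          x0 <- cx + (j - (n + 1) / 2) * size * 0.18
          y0 <- cx - size * 0.18 + row * size * 0.18
          paint(disk(x0, y0, size * 0.10), c(0.45, 0.10, 0.60))
        }
      }
    },
    banana = {
      big <- disk(cx, cx - size * 0.10, size * 0.38)
      cut <- disk(cx, cx - size * 0.26, size * 0.34)
      paint(big & !cut & ys > cx - size * 0.15, c(0.95, 0.85, 0.10))
    },
    stop("no procedural image defined for chunk '", name, "'")
  )
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim = dim(img))
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  img
}

#' Gaussian-noise image used as the image-channel random segment
#'
#' @param size square image edge in pixels.
#' @param mean,sd pixel distribution parameters; values are clipped to
#'   \[0, 1\].
#' @return A `size x size x 3` array.
#' @export
noise_image <- function(size = 60, mean = 0.5, sd = 0.3) {
  img <- array(stats::rnorm(size * size * 3, mean, sd), dim = c(size, size, 3))
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Encode a letter sequence as text-tone input lines
#'
#' Each letter occupies one fixed-duration slot during which its input line
#' (and only that line) carries a rectangular pulse of height
#' `pulse_amplitude` over the leading `pulse_fraction` of the slot; the
#' rest of the slot is silent.
#'
#' @param text letters to encode: a character vector of single letters, or a
#'   single string that is split into letters.
#' @param stim [stim_params()].
#' @return A `time x length(alphabet)` matrix (time in steps of `stim$dt`).
#' @export
encode_text <- function(text, stim = stim_params()) {
  if (length(text) == 1 && nchar(text) > 1)
    text <- strsplit(text, "")[[1]]
  if (length(text) == 0) stop("cannot encode an empty letter sequence")
  idx <- match(text, stim$alphabet)
  if (anyNA(idx))
    stop("unknown letter(s): ",
         paste(unique(text[is.na(idx)]), collapse = ", "))
  slot <- round(stim$letter_slot_ms / stim$dt)
  on <- max(1L, round(slot * stim$pulse_fraction))
  out <- matrix(0, nrow = slot * length(idx), ncol = length(stim$alphabet))
  for (j in seq_along(idx)) {
    rows <- (j - 1L) * slot + seq_len(on)
    out[rows, idx[j]] <- stim$pulse_amplitude
  }
  out
}

#' Encode an RGB image as a 30-dimensional scanned time series
#'
#' The image is decomposed into its R, G and B components; each component is
#' divided into `sections` horizontal bands (top to bottom); each band is
#' scanned left to right by a window of `window_px` columns and mean-pooled,
#' producing one value per channel, band and time step. Output line
#' `(channel - 1) * sections + band` carries that band's pooled scan. The
#' number of scan positions equals `n_steps` so the image-series duration
#' matches the paired text-tone duration.
#'
#' @param image `h x w x 3` array.
#' @param n_steps output duration in time steps.
#' @param stim [stim_params()].
#' @return A `n_steps x (3 * sections)` matrix.
#' @export
encode_image <- function(image, n_steps, stim = stim_params()) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("image must be an RGB array (h x w x 3)")
  h <- d[1]; w <- d[2]
  ns <- stim$sections
  if (h %% ns != 0)
    stop("image height (", h, ") is not divisible into ", ns, " sections")
  band <- h %/% ns
  wp <- min(stim$window_px, w)
  out <- matrix(0, nrow = n_steps, ncol = 3L * ns)
  # left-to-right window start positions, one per time step
  starts <- if (n_steps == 1) 1L else
    1L + round((seq_len(n_steps) - 1) / (n_steps - 1) * (w - wp))
  for (ch in 1:3) {
    comp <- image[, , ch]
    for (s in seq_len(ns)) {
      rows <- (s - 1L) * band + seq_len(band)
      col_idx <- (ch - 1L) * ns + s
      for (t in seq_len(n_steps)) {
        win <- starts[t] + seq_len(wp) - 1L
        out[t, col_idx] <- mean(comp[rows, win])
      }
    }
  }
  out
}

#' Draw one paired random segment
#'
#' The text side encodes a uniformly random letter string whose length is
#' drawn uniformly from `len_range`; the image side encodes a fresh
#' Gaussian-noise image over the same duration, so the two sides are drawn
#' jointly with a common epoch length.
#'
#' @param stim [stim_params()].
#' @param len_range inclusive range of the random letter-string length.
#' @return A list with `modality1`, `modality2` and `n_letters`.
#' @export
make_random_segment <- function(stim = stim_params(), len_range = c(5, 8)) {
  n <- sample(seq(len_range[1], len_range[2]), 1)
  txt <- sample(stim$alphabet, n, replace = TRUE)
  m1 <- encode_text(txt, stim)
  m2 <- encode_image(noise_image(stim$image_size), nrow(m1), stim)
  list(modality1 = m1, modality2 = m2, n_letters = n)
}

#' Assemble a two-modality stimulus track from a chunk schedule
#'
#' Draws `C` presentation epochs. With separators on, random-sequence epochs
#' alternate with chunk epochs (starting with a random segment); with
#' separators off every epoch is a chunk. Chunk identities are i.i.d. draws
#' from `schedule$chunk_probabilities`. The two modalities of each epoch are
#' duration-aligned, and the annotations tile the whole track.
#'
#' @param schedule [schedule_params()]. `m` and `d` are *not* applied here;
#'   see [apply_missing()] and [apply_delay()] or [generate_track()].
#' @param chunks named list of [chunk_spec()] objects.
#' @param stim [stim_params()].
#' @return An object of class `rc_track`: list with matrices `modality1`
#'   (`time x 26`), `modality2` (`time x 30`), a data frame `annotations`
#'   (label, onset_ms, offset_ms, co_occurring, applied_delay_ms) and `dt`.
#' @export
build_sequence <- function(schedule, chunks, stim = stim_params()) {
  stopifnot(inherits(schedule, "rc_schedule_params"), length(chunks) > 0)
  C <- schedule$C
  is_chunk <- if (schedule$use_separators)
    seq_len(C) %% 2 == 0 else rep(TRUE, C)
  picks <- sample(length(chunks), sum(is_chunk), replace = TRUE,
                  prob = schedule$chunk_probabilities)
  segs <- vector("list", C)
  labels <- character(C)
  ki <- 0
  for (e in seq_len(C)) {
    if (is_chunk[e]) {
      ki <- ki + 1
      ch <- chunks[[picks[ki]]]
      img <- ch$image
      if (stim$image_noise_sd > 0) {
        img <- img + array(stats::rnorm(length(img), 0, stim$image_noise_sd),
                           dim = dim(img))
        img[img < 0] <- 0; img[img > 1] <- 1
      }
      m1 <- encode_text(ch$letters, stim)
      segs[[e]] <- list(modality1 = m1,
                        modality2 = encode_image(img, nrow(m1), stim))
      labels[e] <- ch$name
    } else {
      segs[[e]] <- make_random_segment(stim)
      labels[e] <- "random"
    }
  }
  durs <- vapply(segs, function(s) nrow(s$modality1), integer(1))
  offs <- cumsum(durs)
  ann <- data.frame(
    label = labels,
    onset_ms = c(0, offs[-C]) * stim$dt,
    offset_ms = offs * stim$dt,
    co_occurring = labels != "random",
    applied_delay_ms = 0
  )
  structure(list(
    modality1 = do.call(rbind, lapply(segs, `[[`, "modality1")),
    modality2 = do.call(rbind, lapply(segs, `[[`, "modality2")),
    annotations = ann, dt = stim$dt
  ), class = "rc_track")
}

epoch_rows <- function(track, e) {
  ann <- track$annotations
  seq(ann$onset_ms[e] / track$dt + 1, ann$offset_ms[e] / track$dt)
}

#' Break stimulus co-occurrence by random pair replacement
#'
#' Independently for each chunk epoch, with probability `m` one modality's
#' signal is replaced by the corresponding signal of a different chunk or by
#' a random segment (the replacement source is chosen uniformly among those
#' alternatives, and the replaced modality uniformly between the two). The
#' replacement is re-encoded at the epoch's duration: image sources are
#' scanned over the epoch length directly, text sources are truncated or
#' zero-padded to it. Replaced epochs get `co_occurring = FALSE`; the label
#' keeps the nominal chunk. `m = 0` returns the track unchanged.
#'
#' @param track an `rc_track`.
#' @param m replacement probability in \[0, 1\].
#' @param chunks the chunk set used to build the track.
#' @param stim [stim_params()].
#' @return The manipulated `rc_track`.
#' @export
apply_missing <- function(track, m, chunks, stim = stim_params()) {
  if (m < 0 || m > 1) stop("replacement probability m must be in [0, 1]")
  if (m == 0) return(track)
  ann <- track$annotations
  chunk_eps <- which(ann$label != "random")
  for (e in chunk_eps) {
    if (stats::runif(1) >= m) next
    rows <- epoch_rows(track, e)
    dur <- length(rows)
    side <- sample(1:2, 1)
    alternatives <- c(setdiff(names(chunks), ann$label[e]), ".random")
    src <- sample(alternatives, 1)
    if (side == 1) {
      seg <- if (src == ".random")
        encode_text(sample(stim$alphabet, sample(5:8, 1), replace = TRUE),
                    stim)
      else encode_text(chunks[[src]]$letters, stim)
      if (nrow(seg) >= dur) seg <- seg[seq_len(dur), , drop = FALSE]
      else seg <- rbind(seg, matrix(0, dur - nrow(seg), ncol(seg)))
      track$modality1[rows, ] <- seg
    } else {
      img <- if (src == ".random") noise_image(stim$image_size)
      else chunks[[src]]$image
      track$modality2[rows, ] <- encode_image(img, dur, stim)
    }
    track$annotations$co_occurring[e] <- FALSE
  }
  track
}

#' Delay one modality's stream relative to the other
#'
#' Shifts the designated modality's whole stream later by `d` ms (a global
#' shift, so every chunk epoch's signal in that channel lags its partner by
#' `d`); the vacated initial span is zero-filled and the trailing `d` ms are
#' dropped. Annotations keep the undelayed epoch boundaries and record the
#' applied delay. `d = 0` is the identity.
#'
#' @param track an `rc_track`.
#' @param d delay in ms (must not exceed the track duration).
#' @param modality which channel to shift (1 = text, 2 = image).
#' @return The delayed `rc_track`.
#' @export
apply_delay <- function(track, d, modality = 2) {
  if (d < 0) stop("delay d must be non-negative")
  if (d == 0) return(track)
  steps <- round(d / track$dt)
  key <- paste0("modality", modality)
  x <- track[[key]]
  if (steps >= nrow(x)) stop("delay d (", d, " ms) exceeds track duration")
  track[[key]] <- rbind(matrix(0, steps, ncol(x)),
                        x[seq_len(nrow(x) - steps), , drop = FALSE])
  track$annotations$applied_delay_ms <- d
  track
}

#' Generate a stimulus track with all schedule manipulations applied
#'
#' Convenience wrapper: [build_sequence()] then [apply_missing()] with
#' `schedule$m` and [apply_delay()] with `schedule$d`.
#'
#' @inheritParams build_sequence
#' @return An `rc_track`.
#' @export
generate_track <- function(schedule, chunks = default_chunks(stim),
                           stim = stim_params()) {
  tr <- build_sequence(schedule, chunks, stim)
  tr <- apply_missing(tr, schedule$m, chunks, stim)
  apply_delay(tr, schedule$d, schedule$delayed_modality)
}

#' @export
print.rc_track <- function(x, ...) {
  ann <- x$annotations
  cat("<rc_track> ", nrow(x$modality1), " steps (dt = ", x$dt, " ms), ",
      nrow(ann), " epochs\n", sep = "")
  print(table(ann$label))
  invisible(x)
}

#' Write a track's annotations to CSV
#'
#' @param track an `rc_track`.
#' @param path output file path.
#' @export
write_annotations <- function(track, path) {
  utils::write.csv(track$annotations, path, row.names = FALSE)
  invisible(path)
}
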