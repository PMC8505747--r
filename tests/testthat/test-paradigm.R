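test_that("tone alphabet follows the equal-temperament formula", {
  ts <- build_tone_set(440, 3, 11)
  expect_equal(round(ts$frequencies, 2),
               c(440, 523.25, 622.25, 739.99, 880, 1046.5, 1244.51,
                 1479.98, 1760, 2093, 2489.02))
  expect_equal(ts$frequencies[ts$d_index] / ts$frequencies[ts$s_index],
               2^(3 / 12), tolerance = 1e-9)
  expect_true(all(diff(ts$frequencies) > 0))
  expect_equal(ts$frequencies[ts$s_index], 880)
  expect_length(ts$filler_indices, 9)

  oct <- build_tone_set(440, 12, 2, s_index = 1, d_index = 2)
  expect_equal(oct$frequencies, c(440, 880))

  expect_error(build_tone_set(-1), "positive")
  expect_error(build_tone_set(440, 3, 1), "at least 2")
})

test_that("microsequences carry the exact role multiset per condition", {
  ts <- build_tone_set()
  set.seed(11)
  for (cond in c("oddball", "high", "low", "random")) {
    sp <- sequence_spec(cond)
    for (i in 1:250) {
      m <- generate_microsequence(sp, ts)
      expect_identical(sum(m$roles == "S"), as.integer(sp$p_s_numerator))
      expect_identical(sum(m$roles == "D"), 1L)
      expect_identical(sum(m$roles == "F"),
                       sp$micro_len - sp$p_s_numerator - 1L)
      expect_true(all(m$tones[m$roles == "S"] == ts$s_index))
      expect_true(all(m$tones[m$roles == "D"] == ts$d_index))
      expect_true(all(m$tones[m$roles == "F"] %in% ts$filler_indices))
    }
  }
})

test_that("fillers are drawn equiprobably (binomial check over 10000 draws)", {
  ts <- build_tone_set()
  sp <- sequence_spec("random")
  set.seed(21)
  n_micro <- 10000L
  counts <- integer(ts$n_tones)
  for (i in seq_len(n_micro)) {
    m <- generate_microsequence(sp, ts)
    counts <- counts + tabulate(m$tones, ts$n_tones)
  }
  # each filler slot samples uniformly over 9 tones; per microsequence there
  # are 9 filler events, so each tone's expected relative frequency among
  # all events is 9/9 * 1/11 = 1/11
  n_events <- n_micro * sp$micro_len
  p0 <- 1 / 11
  se <- sqrt(p0 * (1 - p0) / n_events)
  for (k in ts$filler_indices) {
    expect_lt(abs(counts[k] / n_events - p0), 3 * se + 1e-12)
  }
})

test_that("full sequences meet the design: length, counts, boundaries, onsets", {
  ts <- build_tone_set()
  sp <- sequence_spec("oddball", seed = 5)
  sq <- generate_sequence(sp, ts)
  expect_length(sq$tone_indices, 1650)
  expect_identical(sum(sq$roles == "S"), 1500L)
  expect_identical(sum(sq$roles == "D"), 150L)
  expect_equal(sq$onsets, (0:1649) * 333)
  expect_equal(mean(sq$roles == "D"), 1 / 11)

  rsp <- sequence_spec("random", seed = 6)
  rsq <- generate_sequence(rsp, ts)
  expect_identical(sum(diff(rsq$tone_indices) == 0L), 0L)

  # determinism: same seed identical, different seed different
  sq2 <- generate_sequence(sp, ts)
  expect_identical(sq$tone_indices, sq2$tone_indices)
  sq3 <- generate_sequence(sequence_spec("oddball", seed = 6), ts)
  expect_false(identical(sq$tone_indices, sq3$tone_indices))
})

test_that("validate_sequence reports planted violations", {
  ts <- build_tone_set()
  sq <- generate_sequence(sequence_spec("random", seed = 9), ts)
  v <- validate_sequence(sq, ts)
  expect_true(attr(v, "ok"))

  # truncation: length check must fail with the observed count
  short <- sq
  short$tone_indices <- short$tone_indices[1:1639]
  short$roles <- short$roles[1:1639]
  short$onsets <- short$onsets[1:1639]
  vs <- validate_sequence(short, ts)
  expect_false(attr(vs, "ok"))
  expect_false(vs$pass[vs$check == "length"])
  expect_identical(vs$observed[vs$check == "length"], "1639")

  # planted boundary repetition under the random spec
  bad <- sq
  b <- bad$micro_boundaries[2]
  bad$tone_indices[b] <- bad$tone_indices[b - 1L]
  vb <- validate_sequence(bad, ts)
  expect_false(vb$pass[vb$check == "boundary repetition rule"])
})

test_that("audio synthesis: duration, ramps, spectral peak, aliasing guard", {
  ts <- build_tone_set()
  sq <- generate_sequence(sequence_spec("oddball", seed = 2,
                                        n_micro = 2L), ts)
  au <- synthesize_audio(sq, ts)
  w <- au$waveforms[["5"]] # 880 Hz standard
  expect_length(w, 2205) # 50 ms at 44100 Hz
  expect_equal(nrow(au$schedule), 22)

  # dominant DFT peak at 880 Hz within one bin
  spec <- abs(fft(w))[1:(length(w) / 2)]
  f_peak <- (which.max(spec) - 1) * 44100 / length(w)
  expect_lt(abs(f_peak - 880), 44100 / length(w))

  # degenerate ramp -> rectangular envelope (peak stays at 1 throughout)
  sq0 <- sq; sq0$spec$ramp <- 0
  w0 <- synthesize_audio(sq0, ts)$waveforms[["5"]]
  expect_equal(max(abs(w0[1:50])), max(abs(w0)), tolerance = 1e-2)

  sq_bad <- sq; sq_bad$spec$audio_rate <- 4000
  expect_error(synthesize_audio(sq_bad, ts), "Nyquist")
})

test_that("sequence TSV export round-trips the event table", {
  ts <- build_tone_set()
  sq <- generate_sequence(sequence_spec("low", seed = 3, n_micro = 5L), ts)
  f <- tempfile(fileext = ".tsv")
  write_sequence_tsv(sq, f, ts)
  df <- read.delim(f)
  expect_equal(nrow(df), 55)
  expect_equal(df$tone_index, sq$tone_indices)
  expect_equal(df$frequency_hz, ts$frequencies[sq$tone_indices])
  expect_equal(unique(df$micro_index), 1:5)
  unlink(f)
})
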