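make_rec <- function(n = 5000, fs = 1000) {
  set.seed(11)
  recording(
    list(lv_pressure = trace(80 + 20 * sin(2 * pi * 1.2 * (1:n) / fs),
                             fs, "mmHg"),
         aortic_pressure = trace(95 + rnorm(n), fs, "mmHg"),
         lv_conductance = trace(100 + 15 * cos(2 * pi * 1.2 * (1:n) / fs),
                                fs, "a.u.")),
    animal_id = "pig03", condition = "P8", meta = list(note = "demo"))
}

test_that("waveform files round-trip recordings exactly enough", {
  rec <- make_rec()
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)

  expect_s3_class(back, "coro_recording")
  expect_identical(names(back$channels), names(rec$channels))
  expect_equal(recording_fs(back), 1000)
  expect_identical(back$condition, "P8")
  expect_identical(back$animal_id, "pig03")
  for (ch in names(rec$channels)) {
    a <- rec$channels[[ch]]; b <- back$channels[[ch]]
    expect_identical(b$unit, a$unit)
    expect_lt(max(abs(b$samples - a$samples) / pmax(abs(a$samples), 1)), 1e-9)
    expect_length(b$samples, 5000)
  }
})

test_that("reader rejects malformed and non-finite input with located errors", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("# fs_hz=100", "a,b", "1,2", "3,4", "5,6", "7,8", "9,10",
               "11,12", "NaN,14", "15,16"), path)
  expect_error(read_recording(path), "row 7", class = "corohemo_validation_error")

  writeLines(c("# fs_hz=100", "a,b", "1,2", "3,4,9"), path)
  expect_error(read_recording(path), "row 2", class = "corohemo_structure_error")

  writeLines(c("# nonsense header", "a,b", "1,2", "3,4"), path)
  expect_error(read_recording(path), "garbled", class = "corohemo_format_error")

  writeLines(c("a,b", "1,2", "3,4"), path)
  expect_error(read_recording(path), "fs_hz", class = "corohemo_format_error")

  expect_error(read_recording(file.path(tempdir(), "nope.csv")),
               class = "corohemo_io_error")
  expect_error(recording(list()), class = "corohemo_validation_error")
  expect_error(trace(c(1, NA, 3), 100), "index 2")
})

test_that("angio annotations parse, normalize and validate", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# frame_rate=30", "vessel,first_fill_frame",
               "lad,42", "LCX,10"), path)
  a <- read_angio_annotation(path)
  expect_equal(a$frame_rate, 30)
  expect_identical(a$fills, c(LAD = 42L, LCX = 10L))

  write_angio_annotation(a, path)
  expect_identical(read_angio_annotation(path)$fills, a$fills)

  writeLines(c("# frame_rate=30", "vessel,first_fill_frame",
               "LAD,42", "LAD,10"), path)
  expect_error(read_angio_annotation(path), "duplicate",
               class = "corohemo_validation_error")

  writeLines(c("# frame_rate=30", "vessel,first_fill_frame", "LAD,4.5"), path)
  expect_error(read_angio_annotation(path), "non-integer",
               class = "corohemo_validation_error")

  writeLines(c("vessel,first_fill_frame", "LAD,42"), path)
  expect_error(read_angio_annotation(path), "frame_rate",
               class = "corohemo_format_error")

  expect_error(angio_annotation(c(LAD = -1, LCX = 3)),
               class = "corohemo_validation_error")
})
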