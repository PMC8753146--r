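test_that("configs validate fail-fast with named keys and round-trip", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(command = "gen-synthetic",
                            params = list(n = 12)), path, auto_unbox = TRUE)
  cfg <- load_config(path)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$seed, 1L)          # default filled
  expect_equal(cfg$out_dir, ".")
  # offending key and constraint are named
  jsonlite::write_json(list(command = "macro-run",
                            params = list(p = 1.5)), path, auto_unbox = TRUE)
  expect_error(load_config(path), "'p' must lie in \\[0,1\\]")
  jsonlite::write_json(list(command = "macro-run", bogus = 1), path,
                       auto_unbox = TRUE)
  expect_error(load_config(path), "unknown config key.*bogus")
  expect_error(validate_config(list(command = "fly-to-moon")),
               "unknown command")
  # write -> read round-trips unchanged (yaml flavour)
  ypath <- withr::local_tempfile(fileext = ".yaml")
  cfg0 <- validate_config(list(command = "gen-synthetic", seed = 9,
                               params = list(n = 7)))
  write_config(cfg0, ypath)
  cfg1 <- load_config(ypath)
  expect_equal(unclass(cfg1), unclass(cfg0))
})

test_that("runs chain through manifests and are byte-reproducible", {
  dir1 <- withr::local_tempdir()
  cfg <- validate_config(list(command = "gen-synthetic", seed = 3,
                              out_dir = dir1, log_level = "quiet",
                              params = list(n = 20)))
  m1 <- run_command(cfg)
  csv <- file.path(dir1, "synthetic_country_table.csv")
  expect_true(file.exists(csv))
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  # identical config + seed: byte-identical CSV
  dir2 <- withr::local_tempdir()
  cfg2 <- cfg; cfg2$out_dir <- dir2
  run_command(cfg2)
  expect_identical(readLines(csv),
                   readLines(file.path(dir2, "synthetic_country_table.csv")))
  # downstream fit records the input checksum, linking the two runs
  dir3 <- withr::local_tempdir()
  cfg3 <- validate_config(list(
    command = "fit-pcr", seed = 1, out_dir = dir3, log_level = "quiet",
    params = list(input = csv)))
  m3 <- run_command(cfg3)
  expect_equal(names(m3$inputs), csv)
  expect_equal(m3$inputs[[csv]], unname(m1$outputs[[csv]]))
  expect_true(file.exists(file.path(dir3, "pcr_fit.json")))
})

test_that("changepoint and macro subcommands emit their artifacts", {
  dir1 <- withr::local_tempdir()
  d <- gen_piecewise_data(piecewise_spec(3, 17, 21, 6.8, x_range = c(1, 10),
                                         n = 60, noise_sd = 3), seed = 2)
  input <- file.path(dir1, "data.csv")
  write.csv(d, input, row.names = FALSE)
  cfg <- validate_config(list(command = "fit-changepoint", out_dir = dir1,
                              log_level = "quiet",
                              params = list(input = input)))
  run_command(cfg)
  rep <- jsonlite::fromJSON(file.path(dir1, "changepoint_fit.json"))
  expect_lt(abs(rep$coefficients$xc - 6.8), 1)
  cfgm <- validate_config(list(
    command = "macro-run", out_dir = dir1, log_level = "quiet",
    params = list(r_star = 0.9, tau1 = 10, T = 20, mu = 6, epsilon = 3e-4,
                  f0 = 0.1, p = 0.005, pv = 0.02, horizon = 50)))
  run_command(cfgm)
  tr <- read.csv(file.path(dir1, "macro_trajectory.csv"))
  expect_equal(nrow(tr), 50)
  expect_true(all(abs(tr$z + tr$d + tr$f - 1) < 1e-9))
})
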