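#' Command-line entry point
#'
#' Dispatches the pipeline subcommands. Intended to be called from the
#' `inst/scripts/osteotex` wrapper (`Rscript -e` works too):
#'
#' * `enhance  --in img.pgm --out clean.pgm [--flatfield 20 --dehaze 0.05 --clip 0.001]`
#' * `features --out features.csv [--config cfg.json] img1.pgm img2.pgm ...`
#' * `scales   --labels labels.csv --out-dir DIR` (DBI candidate report;
#'   `labels.csv` has columns `file`, `label` with image paths)
#' * `select   --features features.csv --out-dir DIR [--rounds 60 --seed 1]`
#' * `train    --train train.csv --test test.csv --out-dir DIR`
#' * `eval     --train train.csv --test test.csv --out-dir DIR` (alias of train)
#' * `simulate --out-dir DIR [--n 30 --size 128 --seed 1]`
#'
#' @param args Character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status 0 invisibly; side effects are written files and
#'   stderr logs.
#' @export
otx_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: osteotex <enhance|features|select|train|eval|simulate> [options]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  rest <- args[-1L]
  switch(cmd,
    enhance = cli_enhance(rest),
    features = cli_features(rest),
    scales = cli_scales(rest),
    select = cli_select(rest),
    train = cli_train(rest),
    eval = cli_train(rest),
    simulate = cli_simulate(rest),
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}

cli_config_from_opts <- function(opt) {
  if (!is.null(opt$config) && nzchar(opt$config)) {
    config_read(opt$config)
  } else {
    pipeline_config(
      flatfield_sigma = opt$flatfield %||% 20,
      dehaze_amount = opt$dehaze %||% 0.05,
      clip = opt$clip %||% 0.001,
      fd_radii = parse_pair(opt$fd_radii %||% "1:4", ":"),
      fd_keep = opt$fd_keep %||% 0.8,
      ent_radii = c(opt$ent_measure %||% 1L, opt$ent_count %||% 6L),
      lac_sizes = parse_pair(opt$lac_sizes %||% "3,4", ","),
      rounds = opt$rounds %||% 60L,
      seed = opt$seed %||% 1L
    )
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_pair <- function(s, sep) as.integer(strsplit(s, sep, fixed = TRUE)[[1L]])

cli_enhance <- function(args) {
  ol <- list(
    optparse::make_option("--in", type = "character", dest = "input"),
    optparse::make_option("--out", type = "character"),
    optparse::make_option("--flatfield", type = "double", default = 20),
    optparse::make_option("--dehaze", type = "double", default = 0.05),
    optparse::make_option("--clip", type = "double", default = 0.001)
  )
  opt <- optparse::parse_args(optparse::OptionParser(option_list = ol), args)
  img <- read_gray_image(opt$input)
  out <- enhance_image(img, opt$flatfield, opt$dehaze, opt$clip)
  write_gray_image(out, opt$out)
  log_stage("enhanced %s -> %s", opt$input, opt$out)
}

cli_features <- function(args) {
  ol <- list(
    optparse::make_option("--out", type = "character"),
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--roi-dir", type = "character", default = NULL,
                          dest = "roi_dir"),
    optparse::make_option("--fd-radii", type = "character", default = "1:4",
                          dest = "fd_radii"),
    optparse::make_option("--fd-keep", type = "double", default = 0.8,
                          dest = "fd_keep"),
    optparse::make_option("--ent-measure", type = "integer", default = 1L,
                          dest = "ent_measure"),
    optparse::make_option("--ent-count", type = "integer", default = 6L,
                          dest = "ent_count"),
    optparse::make_option("--lac-sizes", type = "character", default = "3,4",
                          dest = "lac_sizes"),
    optparse::make_option("--flatfield", type = "double", default = 20),
    optparse::make_option("--dehaze", type = "double", default = 0.05),
    optparse::make_option("--clip", type = "double", default = 0.001),
    optparse::make_option("--seed", type = "integer", default = 1L)
  )
  opt <- optparse::parse_args(optparse::OptionParser(option_list = ol), args,
                              positional_arguments = TRUE)
  cfg <- cli_config_from_opts(opt$options)
  imgs <- opt$args
  rois <- NULL
  if (!is.null(opt$options$roi_dir)) {
    cand <- file.path(opt$options$roi_dir,
                      paste0(tools::file_path_sans_ext(basename(imgs)), ".json"))
    rois <- ifelse(file.exists(cand), cand, NA_character_)
  }
  res <- run_extract(cfg, imgs, rois, out_csv = opt$options$out)
  fails <- attr(res, "failures")
  if (length(fails)) log_stage("%d file(s) failed", length(fails))
}

cli_scales <- function(args) {
  ol <- list(
    optparse::make_option("--labels", type = "character"),
    optparse::make_option("--out-dir", type = "character", dest = "out_dir")
  )
  opt <- optparse::parse_args(optparse::OptionParser(option_list = ol), args)
  tab <- read.csv(opt$labels)
  if (!all(c("file", "label") %in% names(tab))) {
    stop("labels CSV needs `file` and `label` columns")
  }
  base <- dirname(opt$labels)
  paths <- ifelse(file.exists(tab$file), tab$file, file.path(base, tab$file))
  imgs <- lapply(paths, read_gray_image)
  sel <- scan_scales(imgs, tab$label, candidate_grid())
  dir.create(opt$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sel$report)) {
    write.csv(sel$report[[nm]], file.path(opt$out_dir, paste0("dbi_", nm, ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(
    list(fd_radii = c(sel$fd$r_min, sel$fd$r_max), entropy = sel$entropy,
         lac_sizes = sel$lac_sizes),
    file.path(opt$out_dir, "selected_scales.json"), auto_unbox = TRUE
  )
  log_stage("scales: fd %d-%d, entropy %d/%d, lacunarity %s",
            sel$fd$r_min, sel$fd$r_max, sel$entropy[1], sel$entropy[2],
            paste(sel$lac_sizes, collapse = ","))
}

cli_select <- function(args) {
  ol <- list(
    optparse::make_option("--features", type = "character"),
    optparse::make_option("--out-dir", type = "character", dest = "out_dir"),
    optparse::make_option("--rounds", type = "integer", default = 60L),
    optparse::make_option("--seed", type = "integer", default = 1L)
  )
  opt <- optparse::parse_args(optparse::OptionParser(option_list = ol), args)
  tab <- feature_table(read.csv(opt$features))
  ballot <- ballot_rank(tab, n_rounds = opt$rounds, seed = opt$seed)
  dir.create(opt$out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(feature = names(ballot$scores),
                       score = as.numeric(ballot$scores)),
            file.path(opt$out_dir, "ballot.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(ballot$selected),
                       file.path(opt$out_dir, "selected_features.json"))
  log_stage("selected: %s", paste(ballot$selected, collapse = ", "))
}

cli_train <- function(args) {
  ol <- list(
    optparse::make_option("--train", type = "character"),
    optparse::make_option("--test", type = "character"),
    optparse::make_option("--out-dir", type = "character", dest = "out_dir"),
    optparse::make_option("--rounds", type = "integer", default = 60L),
    optparse::make_option("--seed", type = "integer", default = 1L)
  )
  opt <- optparse::parse_args(optparse::OptionParser(option_list = ol), args)
  cfg <- pipeline_config(rounds = opt$rounds, seed = opt$seed)
  res <- run_train_eval(cfg, opt$train, opt$test, out_dir = opt$out_dir)
  print(res$report)
}

cli_simulate <- function(args) {
  ol <- list(
    optparse::make_option("--out-dir", type = "character", dest = "out_dir"),
    optparse::make_option("--n", type = "integer", default = 30L),
    optparse::make_option("--size", type = "integer", default = 128L),
    optparse::make_option("--seed", type = "integer", default = 1L)
  )
  opt <- optparse::parse_args(optparse::OptionParser(option_list = ol), args)
  spec <- cohort_spec(n_per_class = opt$n, image_size = opt$size,
                      seed = opt$seed)
  coh <- make_cohort(spec)
  dir.create(opt$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(coh$images)) {
    write_gray_image(coh$images[[i]],
                     file.path(opt$out_dir, sprintf("img_%03d.pgm", i)))
  }
  write.csv(cbind(data.frame(file = sprintf("img_%03d.pgm",
                                            seq_along(coh$images))),
                  coh$features),
            file.path(opt$out_dir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(spec), file.path(opt$out_dir, "spec.json"),
                       digits = NA, auto_unbox = TRUE)
  log_stage("wrote %d images to %s", length(coh$images), opt$out_dir)
}
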