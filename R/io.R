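#' Write trajectory sequences to delimited text
#'
#' One CSV per sequence with columns `t, x0, x1, bias, target, state`
#' (0-based time index), plus a JSON manifest recording the configuration,
#' noise condition and seeds.
#'
#' @param seqs list of `trajectory_sequence` objects.
#' @param dir output directory (created if missing).
#' @param cfg the [env_config()] that generated the sequences.
#' @param prefix file-name prefix.
#' @return invisibly, the manifest path.
#' @export
write_sequences <- function(seqs, dir, cfg, prefix = "seq") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    df <- data.frame(t = seq_len(nrow(s$x)) - 1L,
                     x0 = s$x[, 1], x1 = s$x[, 2],
                     bias = s$truth$bias, target = s$truth$target,
                     state = s$truth$state)
    files[i] <- sprintf("%s_%03d.csv", prefix, i)
    write.csv(df, file.path(dir, files[i]), row.names = FALSE)
  }
  manifest <- list(
    files = files,
    config = cfg[setdiff(names(cfg), "centers")],
    centers = cfg$centers,
    meta = lapply(seqs, function(s) s$meta))
  mpath <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Read trajectory sequences written by [write_sequences()]
#'
#' @param dir directory holding the CSV files and manifest.
#' @param prefix file-name prefix used when writing.
#' @return list of `trajectory_sequence` objects.
#' @export
read_sequences <- function(dir, prefix = "seq") {
  manifest <- jsonlite::read_json(file.path(dir, paste0(prefix, "_manifest.json")),
                                  simplifyVector = TRUE)
  lapply(seq_along(manifest$files), function(i) {
    df <- read.csv(file.path(dir, manifest$files[i]), stringsAsFactors = FALSE)
    meta <- if (is.data.frame(manifest$meta)) as.list(manifest$meta[i, ])
            else manifest$meta[[i]]
    structure(list(x = cbind(df$x0, df$x1),
                   truth = data.frame(bias = df$bias, target = df$target,
                                      state = df$state, stringsAsFactors = FALSE),
                   meta = meta),
              class = "trajectory_sequence")
  })
}
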