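#' Read a MOTChallenge-style file
#'
#' Parses comma-separated rows
#' `frame, id, bb_left, bb_top, bb_width, bb_height, conf, x, y, z`
#' (pixel top-left coordinates, 1-based frames) into the package's internal
#' convention: 0-based frames and normalized center-format boxes. Rows are
#' validated; a malformed row aborts with its line number.
#'
#' @param path File path.
#' @param dialect `"det"` (id ignored, confidence kept), `"gt"` or
#'   `"result"` (ids kept).
#' @param image_size Pixel dimensions `c(width, height)` used to normalize.
#' @return A tibble with `frame`, `id` (absent for `"det"`), `cx, cy, w, h`
#'   and `conf`.
#' @export
read_mot <- function(path, dialect = c("det", "gt", "result"), image_size) {
  dialect <- match.arg(dialect)
  if (missing(image_size) || is.null(image_size)) {
    stop("image_size is required to normalize pixel coordinates", call. = FALSE)
  }
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- tibble::tibble(
      frame = integer(), id = integer(), cx = numeric(), cy = numeric(),
      w = numeric(), h = numeric(), conf = numeric()
    )
    if (dialect == "det") out$id <- NULL
    return(out)
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  n_ok <- vapply(parts, length, integer(1)) >= 7L
  if (any(!n_ok)) {
    stop("malformed row (expected >= 7 comma-separated fields) at line ",
      which(!n_ok)[1],
      call. = FALSE
    )
  }
  num <- lapply(seq_along(parts), function(i) {
    v <- suppressWarnings(as.numeric(parts[[i]][1:7]))
    if (any(is.na(v))) stop("non-numeric field at line ", i, call. = FALSE)
    v
  })
  m <- do.call(rbind, num)
  bad <- which(m[, 5] <= 0 | m[, 6] <= 0)
  if (length(bad)) {
    stop("non-positive box dimensions at line ", bad[1], call. = FALSE)
  }
  if (is.unsorted(m[, 1])) stop("frame numbers must be non-decreasing", call. = FALSE)
  W <- image_size[1]; H <- image_size[2]
  out <- tibble::tibble(
    frame = as.integer(m[, 1]) - 1L,
    id = as.integer(m[, 2]),
    cx = (m[, 3] + m[, 5] / 2) / W,
    cy = (m[, 4] + m[, 6] / 2) / H,
    w = m[, 5] / W,
    h = m[, 6] / H,
    conf = m[, 7]
  )
  if (dialect == "det") out$id <- NULL
  out
}

#' Write a MOTChallenge-style file
#'
#' Inverse of [read_mot()]: converts internal 0-based normalized
#' center-format records to 1-based pixel top-left rows. Ground-truth files
#' carry their ids and confidence 1; detection files carry id -1 and their
#' confidences; result files carry ids and confidences.
#'
#' @param x Tibble with `frame`, `cx, cy, w, h`, and `id`/`conf` as the
#'   dialect requires.
#' @param path Output path.
#' @param dialect `"det"`, `"gt"` or `"result"`.
#' @param image_size Pixel dimensions `c(width, height)`.
#' @return `path`, invisibly.
#' @export
write_mot <- function(x, path, dialect = c("det", "gt", "result"), image_size) {
  dialect <- match.arg(dialect)
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  W <- image_size[1]; H <- image_size[2]
  if (nrow(x) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  id <- if (dialect == "det") rep(-1L, nrow(x)) else x$id
  conf <- if (dialect == "gt") rep(1, nrow(x)) else x$conf
  rows <- sprintf(
    "%d,%d,%.6f,%.6f,%.6f,%.6f,%.6f,-1,-1,-1",
    x$frame + 1L, id,
    x$cx * W - x$w * W / 2, x$cy * H - x$h * H / 2,
    x$w * W, x$h * H, conf
  )
  writeLines(rows, path)
  invisible(path)
}

#' Write / read the detection feature sidecar
#'
#' The sidecar is a comma-separated table keyed by `(frame, det)` — `det`
#' being the 1-based detection index within its frame — with one column per
#' appearance-embedding component (`app_1 ...`) and per flow-histogram bin
#' (`hist_1 ...`). [attach_features()] joins it back onto a detection table
#' read with [read_mot()].
#'
#' @param dets Detection tibble with list-columns `app` and/or `fhist`.
#' @param path Sidecar path.
#' @return `write_features()`: `path`, invisibly. `read_features()`: a
#'   tibble with `frame`, `det` and list-columns `app`, `fhist`.
#' @export
write_features <- function(dets, path) {
  if (nrow(dets) == 0L) {
    writeLines("frame,det", path)
    return(invisible(path))
  }
  det_idx <- stats::ave(seq_len(nrow(dets)), dets$frame, FUN = seq_along)
  app <- if ("app" %in% names(dets)) do.call(rbind, dets$app) else NULL
  fh <- if ("fhist" %in% names(dets)) do.call(rbind, dets$fhist) else NULL
  df <- data.frame(frame = dets$frame, det = det_idx)
  if (!is.null(app)) {
    colnames(app) <- paste0("app_", seq_len(ncol(app)))
    df <- cbind(df, app)
  }
  if (!is.null(fh)) {
    colnames(fh) <- paste0("hist_", seq_len(ncol(fh)))
    df <- cbind(df, fh)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  app_cols <- grep("^app_", names(df))
  hist_cols <- grep("^hist_", names(df))
  out <- tibble::tibble(frame = as.integer(df$frame), det = as.integer(df$det))
  if (length(app_cols)) {
    out$app <- lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, app_cols]))
  }
  if (length(hist_cols)) {
    out$fhist <- lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, hist_cols]))
  }
  out
}

#' @rdname write_features
#' @param feats A tibble from [read_features()].
#' @export
attach_features <- function(dets, feats) {
  det_idx <- stats::ave(seq_len(nrow(dets)), dets$frame, FUN = seq_along)
  key <- paste(dets$frame, det_idx)
  fkey <- paste(feats$frame, feats$det)
  pos <- match(key, fkey)
  if ("app" %in% names(feats)) dets$app <- feats$app[pos]
  if ("fhist" %in% names(feats)) dets$fhist <- feats$fhist[pos]
  dets
}

#' Save / load a trained predictor checkpoint
#'
#' Serializes the model parameters and the full configuration to JSON
#' (plain text, full double precision) so a run can be reproduced from its
#' artifacts alone.
#'
#' @param model An `aquatrack_predictor`.
#' @param path Checkpoint path.
#' @return `save_predictor()`: `path`, invisibly. `load_predictor()`: the
#'   restored `aquatrack_predictor`.
#' @export
save_predictor <- function(model, path) {
  stopifnot(inherits(model, "aquatrack_predictor"))
  flat <- nn_flatten(model$params[c("geom", "motion", "dec")])
  payload <- list(
    config = model$config[setdiff(names(model$config), c())],
    params = lapply(flat, function(p) list(dim = dim(p) %||% length(p), data = as.numeric(p))),
    log = if (is.null(model$log)) NULL else as.list(model$log)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(predictor_config, payload$config[names(payload$config) %in% names(formals(predictor_config))])
  set.seed(cfg$seed)
  params <- nn_model_init(cfg)
  flat <- nn_flatten(params[c("geom", "motion", "dec")])
  for (k in names(flat)) {
    p <- payload$params[[k]]
    v <- as.numeric(p$data)
    flat[[k]] <- if (length(p$dim) == 2L) matrix(v, p$dim[1], p$dim[2]) else v
  }
  out <- nn_apply_flat(params[c("geom", "motion", "dec")], flat)
  out$pe <- params$pe
  log <- if (!is.null(payload$log)) tibble::tibble(epoch = payload$log$epoch, loss = payload$log$loss) else NULL
  new_predictor(out, cfg, log = log)
}

#' Write / read a tracker run configuration
#'
#' YAML round-trip of a [tracker_config()] (minus any in-memory predictor,
#' which is referenced by checkpoint path instead). Unknown keys in a read
#' configuration are rejected.
#'
#' @param config A [tracker_config()].
#' @param path YAML path.
#' @param predictor_checkpoint Optional checkpoint path recorded alongside.
#' @return `write_run_config()`: `path` invisibly; `read_run_config()`: a
#'   `tracker_config`.
#' @export
write_run_config <- function(config, path, predictor_checkpoint = NULL) {
  stopifnot(inherits(config, "tracker_config"))
  lst <- unclass(config)
  lst$predictor <- NULL
  lst$biou <- unclass(lst$biou)
  lst$matcher <- unclass(lst$matcher)
  if (!is.null(predictor_checkpoint)) lst$predictor_checkpoint <- predictor_checkpoint
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  ckpt <- lst$predictor_checkpoint
  lst$predictor_checkpoint <- NULL
  known <- names(formals(tracker_config))
  unknown <- setdiff(names(lst), c(known, "biou", "matcher"))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(lst$biou)) lst$biou <- do.call(biou_params, lst$biou)
  if (!is.null(lst$matcher)) lst$matcher <- do.call(matcher_params, lst$matcher)
  cfg <- do.call(tracker_config, lst)
  if (!is.null(ckpt) && file.exists(ckpt)) cfg$predictor <- load_predictor(ckpt)
  cfg
}
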