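#' Read a multichannel delimited time-series file
#'
#' Reads CSV/TSV/whitespace-delimited numeric data, one column per channel
#' and one row per sample. The delimiter and the presence of a header row
#' are auto-detected unless given. Missing or non-numeric cells are
#' rejected with their location.
#'
#' @param path file path.
#' @param sep field separator; `NULL` auto-detects among comma, tab and
#'   whitespace from the first line.
#' @param header logical; `NA` (default) auto-detects by checking whether
#'   the first row parses as numbers.
#' @return Numeric matrix (samples x channels) with channel names as
#'   column names.
#' @export
read_multichannel <- function(path, sep = NULL, header = NA) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (!length(first)) stopf("empty file: %s", path)
  if (is.null(sep)) {
    sep <- if (grepl(",", first, fixed = TRUE)) "," else
           if (grepl("\t", first, fixed = TRUE)) "\t" else ""
  }
  split1 <- function(line) {
    f <- if (sep == "") strsplit(trimws(line), "[[:space:]]+")[[1L]]
         else strsplit(line, sep, fixed = TRUE)[[1L]]
    trimws(f)
  }
  if (is.na(header)) {
    fields <- split1(first)
    header <- anyNA(suppressWarnings(as.numeric(fields)))
  }
  df <- utils::read.table(path, sep = if (sep == "") "" else sep,
                          header = header, colClasses = "character",
                          strip.white = TRUE, check.names = FALSE)
  M <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stopf("non-numeric or missing value at row %d, column %d ('%s')",
            bad[1L], j, df[bad[1L], j])
    M[, j] <- v
  }
  colnames(M) <- if (header) names(df) else paste0("ch", seq_len(ncol(df)))
  M
}

estimate_to_df <- function(est) {
  if (inherits(est, "dcca_estimate")) {
    ns <- length(est$scales)
    rbind(
      data.frame(t = est$t, i = 1L, j = 2L, scale = est$scales,
                 F2 = est$F2_xy, rho = est$rho, alpha = NA_real_),
      data.frame(t = est$t, i = 1L, j = 1L, scale = est$scales,
                 F2 = est$F2_x, rho = rep(1, ns), alpha = est$alpha_x),
      data.frame(t = est$t, i = 2L, j = 2L, scale = est$scales,
                 F2 = est$F2_y, rho = rep(1, ns), alpha = est$alpha_y))
  } else if (inherits(est, "dcca_multi_estimate")) {
    K <- dim(est$F2)[1L]
    ut <- which(upper.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
    do.call(rbind, lapply(seq_along(est$scales), function(q) {
      data.frame(t = est$t, i = ut[, 1L], j = ut[, 2L],
                 scale = est$scales[q],
                 F2 = est$F2[, , q][ut],
                 rho = est$rho[, , q][ut],
                 alpha = ifelse(ut[, 1L] == ut[, 2L],
                                est$alpha[ut[, 1L]], NA_real_))
    }))
  } else stopf("not a streaming estimate")
}

df_to_estimate <- function(df) {
  K <- max(df$j)
  scales <- sort(unique(df$scale))
  ns <- length(scales)
  if (K == 2L && all(df$i <= 2L) &&
      nrow(df) == 3L * ns && sum(df$i != df$j) == ns) {
    xy <- df[df$i == 1L & df$j == 2L, ][order(df$scale[df$i == 1L & df$j == 2L]), ]
    xx <- df[df$i == 1L & df$j == 1L, ]
    yy <- df[df$i == 2L & df$j == 2L, ]
    xx <- xx[order(xx$scale), ]; yy <- yy[order(yy$scale), ]; xy <- xy[order(xy$scale), ]
    structure(list(t = df$t[1L], scales = scales,
                   F2_xy = xy$F2, F2_x = xx$F2, F2_y = yy$F2,
                   rho = xy$rho,
                   alpha_x = xx$alpha[1L], alpha_y = yy$alpha[1L]),
              class = "dcca_estimate")
  } else {
    F2 <- array(NA_real_, c(K, K, ns))
    rho <- array(NA_real_, c(K, K, ns))
    alpha <- rep(NA_real_, K)
    for (r in seq_len(nrow(df))) {
      q <- match(df$scale[r], scales)
      i <- df$i[r]; j <- df$j[r]
      F2[i, j, q] <- F2[j, i, q] <- df$F2[r]
      rho[i, j, q] <- rho[j, i, q] <- df$rho[r]
      if (i == j) alpha[i] <- df$alpha[r]
    }
    out <- structure(list(t = df$t[1L], scales = scales, F2 = F2, rho = rho,
                          alpha = alpha, channels = paste0("ch", seq_len(K))),
                     class = "dcca_multi_estimate")
    out
  }
}

#' Write streaming estimates to disk
#'
#' Serializes a list of streaming estimates as tidy CSV (one row per
#' emission, channel pair and scale: `t, i, j, scale, F2, rho, alpha`,
#' upper triangle plus diagonal) or as JSON lines (one emission per line).
#' Numbers are written with 17 significant digits so a read-back through
#' [read_estimates()] reproduces every double bit-exactly.
#'
#' @param estimates a single estimate or list of estimates as returned by
#'   [stream_push()] / [stream_estimate()].
#' @param path output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return Invisibly, `path`.
#' @export
write_estimates <- function(estimates, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (inherits(estimates, c("dcca_estimate", "dcca_multi_estimate")))
    estimates <- list(estimates)
  if (format == "csv") {
    header <- "t,i,j,scale,F2,rho,alpha"
    rows <- unlist(lapply(estimates, function(est) {
      df <- estimate_to_df(est)
      sprintf("%s,%d,%d,%s,%s,%s,%s",
              fmt_num(df$t), df$i, df$j, fmt_num(df$scale),
              fmt_num(df$F2), fmt_num(df$rho), fmt_num(df$alpha))
    }))
    writeLines(c(header, rows), path)
  } else {
    lines <- vapply(estimates, function(est) {
      jsonlite::toJSON(unclass(est), digits = I(17), auto_unbox = TRUE,
                       na = "null")
    }, "")
    writeLines(lines, path)
  }
  invisible(path)
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Read streaming estimates back from disk
#'
#' Inverse of [write_estimates()]; reconstructs the list of estimate
#' objects from a tidy CSV or JSON-lines file.
#'
#' @param path file written by [write_estimates()].
#' @param format `"csv"` or `"jsonl"`.
#' @return List of estimates (possibly empty).
#' @export
read_estimates <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path)
    if (!nrow(df)) return(list())
    lapply(split(df, df$t), df_to_estimate)
  } else {
    lines <- readLines(path)
    lapply(lines, function(l) {
      o <- jsonlite::fromJSON(l)
      if (!is.null(o$F2) && is.list(dim(o$F2))) o$F2 <- simplify2array(o$F2)
      if (!is.null(o$F2_xy)) {
        structure(o[c("t", "scales", "F2_xy", "F2_x", "F2_y", "rho",
                      "alpha_x", "alpha_y")], class = "dcca_estimate")
      } else {
        o$F2 <- array(unlist(o$F2), dim = c(length(o$alpha), length(o$alpha),
                                            length(o$scales)))
        o$rho <- array(unlist(o$rho), dim = dim(o$F2))
        structure(o[c("t", "scales", "F2", "rho", "alpha", "channels")],
                  class = "dcca_multi_estimate")
      }
    })
  }
}
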