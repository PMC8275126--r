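# Two-sample Wilcoxon-Mann-Whitney test with the significance-star
# annotation used throughout the figures, and run-report assembly.

#' Two-sided Mann-Whitney U test
#'
#' For small samples (`n1 + n2 <= 12`) without ties the exact null
#' distribution of U is built by enumerating all rank assignments;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. The two-sided p-value counts assignments at least
#' as extreme in either direction.
#'
#' @param a,b numeric samples (each of size >= 2).
#' @return list of class `stat_result`: `u_statistic` (the smaller of the
#'   two U values), `p_value`, `n1`, `n2`, `stars`, `method`.
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each sample needs at least 2 values")
  pooled <- c(a, b)
  r <- rank(pooled)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u_min <- min(u1, u2)
  ties <- any(duplicated(pooled))
  if (length(unique(pooled)) == 1L) {
    p <- 1
    method <- "degenerate"
  } else if (n1 + n2 <= 12L && !ties) {
    idx <- combn(n1 + n2, n1)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, mean(pmin(us, n1 * n2 - us) <= u_min))
    method <- "exact"
  } else {
    N <- n1 + n2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- (u_min - n1 * n2 / 2 + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(z))
    method <- "normal-approximation"
  }
  structure(list(u_statistic = u_min, p_value = p, n1 = n1, n2 = n2,
                 stars = stars(p), method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> U = %g, p = %.4g (%s), n = %d vs %d  [%s]\n",
              x$u_statistic, x$p_value, x$stars, x$n1, x$n2, x$method))
  invisible(x)
}

#' Significance-star annotation
#'
#' The figure convention: `ns` for 0.05 <= p <= 1, `*` for
#' 0.01 <= p < 0.05, `**` for 0.001 <= p < 0.01, `***` for
#' 0.0001 <= p < 0.001, `****` for p < 0.0001. A p-value exactly at a
#' boundary takes the less significant label.
#'
#' @param p p-value in `[0, 1]`.
#' @return one of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
stars <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single value in [0, 1]")
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 1e-2) "**"
  else if (p < 0.05) "*"
  else "ns"
}

# small stable polynomial hash of a configuration (no binary dependencies;
# doubles stay exact below 2^53 so the modular arithmetic is lossless)
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 4294967291
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Assemble a run report
#'
#' Collects the outputs of any subset of pipeline stages (`onset`,
#' `morphometry`, `motility`, `directionality`, `stats`) into one
#' machine-readable report, stamped with the package version, the
#' parameters used and their configuration hash. Stages not present are
#' marked absent.
#'
#' @param results named list of stage outputs; must contain at least one
#'   recognized stage.
#' @param parameters named list of parameters to echo into the report.
#' @param path optional file path; if given, the report is written there
#'   as JSON (and a plain-text summary next to it with extension `.txt`).
#' @return the report list, invisibly if written to file.
#' @export
build_report <- function(results, parameters = list(), path = NULL) {
  stages <- c("onset", "morphometry", "motility", "directionality", "stats")
  stopifnot(is.list(results))
  unknown <- setdiff(names(results), stages)
  if (length(unknown)) stop("unknown stage(s) in bundle: ", paste(unknown, collapse = ", "))
  present <- intersect(stages, names(results))
  if (!length(present)) stop("empty results bundle: no recognized stage output")
  report <- list(
    software = list(package = "ovquant",
                    version = as.character(packageVersion("ovquant"))),
    parameters = parameters,
    config_hash = config_hash(parameters),
    stages = stats::setNames(lapply(stages, function(s)
      if (s %in% present) results[[s]] else list(status = "absent")), stages)
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    txt <- c("ovquant run report",
             paste0("version: ", report$software$version),
             paste0("config_hash: ", report$config_hash),
             paste0("stages present: ", paste(present, collapse = ", ")))
    writeLines(txt, sub("\\.json$", ".txt", path))
    return(invisible(report))
  }
  report
}
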