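# Dataset ingestion and validation, result writing, display formatting.

# Validate (and standardize) a long-format meta-analytic dataset:
# one row per subject, columns trial, subject, z, x/x1..xp (optional),
# s, t (t may be NA -- an ongoing trial's missing true endpoint).
.validate_meta <- function(data, allow_missing_t = TRUE) {
  data <- as.data.frame(data)
  need <- c("trial", "subject", "z", "s", "t")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("dataset lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!(data$z %in% c(0, 1)))
  if (length(bad))
    stop("non-binary treatment indicator z on row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(is.na(data$s) | !is.finite(data$s))
  if (length(bad))
    stop("missing or non-numeric surrogate s on row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (!allow_missing_t && anyNA(data$t))
    stop("missing true endpoint t on row(s) ",
         paste(utils::head(which(is.na(data$t)), 5), collapse = ", "),
         call. = FALSE)
  key <- paste(data$trial, data$subject, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated (trial, subject) key on row(s) ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  xcols <- intersect(c("x", paste0("x", seq_len(16))), names(data))
  for (xc in xcols) {
    if (anyNA(data[[xc]]))
      stop("missing covariate ", xc, " on row(s) ",
           paste(utils::head(which(is.na(data[[xc]])), 5), collapse = ", "),
           call. = FALSE)
  }
  attr(data, "n_covariates") <- length(xcols)
  data
}

#' Read a long-format meta-analytic dataset
#'
#' Reads a comma- or tab-delimited text file with a header, maps its
#' columns onto the required layout and validates it: `z` must be 0/1, `s`
#' must never be missing, `t` may be empty or `NA` (flagged missing — an
#' ongoing trial), `(trial, subject)` must be unique. Any other non-numeric
#' `t` entry is an error, not silently treated as missing.
#'
#' @param path file path; the delimiter is inferred from the header line.
#' @param columns named list mapping required names (`trial`, `subject`,
#'   `z`, `x`, `s`, `t`) to the file's column names; identity by default.
#'   Omit `x` for an unadjusted (zero-covariate) analysis.
#' @param quiet suppress the per-trial summary message.
#' @return validated data frame with standardized column names and a
#'   `n_covariates` attribute.
#' @export
read_meta <- function(path, columns = NULL, quiet = FALSE) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", na.strings = character(0),
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(columns)) {
    for (std in names(columns)) {
      src <- columns[[std]]
      if (!(src %in% names(raw)))
        stop("mapped column '", src, "' (for ", std, ") not in file",
             call. = FALSE)
      names(raw)[names(raw) == src] <- std
    }
  }
  need <- c("trial", "subject", "z", "s", "t")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("unmapped required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  num <- function(col, allow_blank = FALSE) {
    v <- trimws(raw[[col]])
    blank <- v == "" | v == "NA"
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!blank & is.na(out))
    if (length(bad))
      stop("non-numeric ", col, " on row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    if (!allow_blank && any(blank))
      stop("missing ", col, " on row(s) ",
           paste(utils::head(which(blank), 5), collapse = ", "), call. = FALSE)
    out
  }
  dat <- data.frame(trial = raw$trial, subject = raw$subject,
                    z = num("z"), stringsAsFactors = FALSE)
  xcols <- intersect(c("x", paste0("x", seq_len(16))), names(raw))
  for (xc in xcols) dat[[xc]] <- num(xc)
  dat$s <- num("s")
  dat$t <- num("t", allow_blank = TRUE)
  dat <- .validate_meta(dat)
  if (!quiet) {
    for (tr in unique(dat$trial)) {
      rows <- dat[dat$trial == tr, ]
      message(sprintf("trial %s: n=%d (treated %d), missing T: %d",
                      tr, nrow(rows), sum(rows$z == 1), sum(is.na(rows$t))))
    }
  }
  dat
}

#' Paper-style display of a probability measure
#'
#' Formats psi values with a fixed number of decimals, capping values above
#' 0.99 as `">0.99"` (the display convention for near-certain measures).
#'
#' @param p numeric vector of probabilities.
#' @param digits decimals for the uncapped display.
#' @param cap display cap (values strictly above it print as `">cap"`).
#' @return character vector.
#' @examples
#' format_psi(c(0.9973, 0.845))  # ">0.99" "0.845"
#' @export
format_psi <- function(p, digits = 3, cap = 0.99) {
  ifelse(is.na(p), NA_character_,
         ifelse(p > cap, paste0(">", format(cap)),
                formatC(p, digits = digits, format = "f")))
}

#' Write a results table to delimited text
#'
#' Tab-separated output with full-precision numeric columns (17 significant
#' digits, so written values round-trip bitwise) plus a `<col>_display`
#' companion for any probability column named, using the `">0.99"`
#' capping convention for near-certain measures.
#'
#' @param results a data frame.
#' @param path output path.
#' @param display_cols columns to add display companions for; by default
#'   any column whose name contains `"psi"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, display_cols = NULL) {
  results <- as.data.frame(results)
  if (is.null(display_cols))
    display_cols <- grep("psi", names(results), value = TRUE)
  for (dc in intersect(display_cols, names(results)))
    results[[paste0(dc, "_display")]] <- format_psi(results[[dc]])
  out <- results
  for (nm in names(out))
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read posterior draws as delimited text
#'
#' Columnar draw files: one row per retained draw, named columns for every
#' fixed effect, every upper-triangle D entry (flat `d_*` keys) and the
#' sigma entries, plus the chain index. Values are written with 17
#' significant digits and round-trip bitwise.
#'
#' @param draws an `sp_draws`.
#' @param path file path.
#' @return `path` (write) / a data frame of draws (read).
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "sp_draws"))
  km <- .d_keymap(draws$scenario)
  Dcols <- vapply(names(km), function(k)
    draws$D[km[[k]][1], km[[k]][2], ], numeric(dim(draws$D)[3]))
  if (!is.matrix(Dcols))
    Dcols <- matrix(Dcols, nrow = 1, dimnames = list(NULL, names(km)))
  df <- data.frame(chain = draws$chain, draws$mu, Dcols,
                   sigma_ss = draws$sigma[1, 1, ],
                   sigma_st = draws$sigma[1, 2, ],
                   sigma_tt = draws$sigma[2, 2, ],
                   check.names = FALSE)
  out <- df
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
}

#' Rebuild a draws object from a columnar draws table
#'
#' Inverse of [write_draws()]: reconstructs the `sp_draws` arrays from the
#' flat named columns, so measure posteriors can be computed from a saved
#' draws file.
#'
#' @param frame data frame as returned by [read_draws()].
#' @param scenario `"S1"` or `"S2"` (determines the D layout).
#' @return an `sp_draws` object.
#' @export
as_sp_draws <- function(frame, scenario = c("S1", "S2")) {
  scenario <- match.arg(scenario)
  q <- if (scenario == "S2") 8L else 4L
  km <- .d_keymap(scenario)
  miss <- setdiff(names(km), names(frame))
  if (length(miss))
    stop("draws table lacks D column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  R <- nrow(frame)
  for (p_try in c(0:2, 4)) {
    nm <- fixed_effect_names(p_try)
    if (all(nm %in% names(frame))) { p <- p_try; break }
  }
  if (!exists("p", inherits = FALSE))
    stop("draws table lacks a complete fixed-effect column set", call. = FALSE)
  mu <- as.matrix(frame[, fixed_effect_names(p), drop = FALSE])
  D <- array(0, c(q, q, R))
  for (k in names(km)) {
    ij <- km[[k]]
    D[ij[1], ij[2], ] <- D[ij[2], ij[1], ] <- frame[[k]]
  }
  sig <- array(0, c(2, 2, R))
  sig[1, 1, ] <- frame$sigma_ss
  sig[1, 2, ] <- sig[2, 1, ] <- frame$sigma_st
  sig[2, 2, ] <- frame$sigma_tt
  structure(list(mu = mu, D = D, sigma = sig,
                 chain = if (!is.null(frame$chain)) frame$chain else rep(1L, R),
                 scenario = scenario, p = p, seed = NA_integer_),
            class = "sp_draws")
}
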