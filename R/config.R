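# Flat key-value serialization of model parameters.
#
# D entries use the field's flat notation derived from the labels
# s=aS, t=aT, a=bS, b=bT, cs=cS, ct=cT, ds=dS, dt=dT:
# single-letter pairs concatenate (d_ss, d_ab), longer labels are joined
# with underscores (d_a_cs, d_ds_dt). Upper-triangle entries only.

.d_key <- function(l1, l2) {
  f1 <- RE_FLAT[[l1]]; f2 <- RE_FLAT[[l2]]
  if (nchar(f1) == 1 && nchar(f2) == 1) paste0("d_", f1, f2)
  else paste("d", f1, f2, sep = "_")
}

.d_keymap <- function(scenario) {
  labs <- .re_labels(scenario)
  q <- length(labs)
  keys <- character(0); idx <- list()
  for (i in seq_len(q)) for (j in i:q) {
    k <- .d_key(labs[i], labs[j])
    keys <- c(keys, k)
    idx[[k]] <- c(i, j)
  }
  idx
}

#' Write model parameters to a flat key-value config file
#'
#' Serializes an [sp_params] object to YAML with flat scalar keys
#' (`scenario`, `n_covariates`, `alpha_S` ... `delta_T`, `d_ss` ...
#' `d_dt_dt`, `sigma_ss`, `sigma_st`, `sigma_tt`), readable by
#' [read_params()].
#'
#' @param params an [sp_params] object.
#' @param path output file path.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "sp_params"))
  out <- c(list(scenario = params$scenario, n_covariates = params$p),
           as.list(params$fixed))
  for (kv in names(km <- .d_keymap(params$scenario)))
    out[[kv]] <- params$D[km[[kv]][1], km[[kv]][2]]
  out$sigma_ss <- params$sigma[1, 1]
  out$sigma_st <- params$sigma[1, 2]
  out$sigma_tt <- params$sigma[2, 2]
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Read model parameters from a flat key-value config file
#'
#' @param path YAML file produced by [write_params()] (or hand-written with
#'   the same keys; missing D entries default to 0, missing diagonal or
#'   sigma entries are an error).
#' @return an [sp_params] object.
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenario)) stop("config lacks 'scenario'", call. = FALSE)
  scenario <- match.arg(cfg$scenario, c("S1", "S2"))
  p <- if (!is.null(cfg$n_covariates)) as.integer(cfg$n_covariates)
       else if (scenario == "S2") 1L
       else if (!is.null(cfg$delta_S)) 1L else 0L
  nm <- fixed_effect_names(p)
  miss <- setdiff(nm, names(cfg))
  if (length(miss))
    stop("config lacks fixed effects: ", paste(miss, collapse = ", "),
         call. = FALSE)
  fixed <- vapply(nm, function(k) as.numeric(cfg[[k]]), 0)
  km <- .d_keymap(scenario)
  q <- if (scenario == "S2") 8L else 4L
  D <- matrix(0, q, q)
  for (k in names(km)) {
    ij <- km[[k]]
    val <- cfg[[k]]
    if (is.null(val)) {
      if (ij[1] == ij[2])
        stop("config lacks D diagonal entry '", k, "'", call. = FALSE)
      val <- 0
    }
    D[ij[1], ij[2]] <- D[ij[2], ij[1]] <- as.numeric(val)
  }
  for (k in c("sigma_ss", "sigma_st", "sigma_tt"))
    if (is.null(cfg[[k]])) stop("config lacks '", k, "'", call. = FALSE)
  sigma <- matrix(c(cfg$sigma_ss, cfg$sigma_st, cfg$sigma_st, cfg$sigma_tt), 2)
  sp_params(scenario, fixed, D, sigma)
}
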