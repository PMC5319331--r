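## map plain climate-variable values onto the (possibly lag-suffixed)
## covariate names a model's specs use; deterministic builds use the same
## value at every lag
expand_climate_values <- function(model, vals) {
  nm <- names(model$climate_spec$mean)
  out <- model$climate_spec$mean
  for (v in nm) {
    base <- sub("_(t|tp1|tm1)$", "", v)
    if (v %in% names(vals)) out[v] <- vals[[v]]
    else if (base %in% names(vals)) out[v] <- vals[[base]]
  }
  out
}

#' Fit a demographic model bundle from life-history data
#'
#' Runs the vital-rate stage of the pipeline: builds the design for each
#' configured response, fits the model (optionally running exhaustive
#' AICc selection over all reduced models of a global model), and
#' assembles the fitted specs with the state space, fecundity parameters
#' and climate distribution into a [sprout_model()].
#'
#' @param table Life history table.
#' @param climate A [climate_series()] or `NULL`.
#' @param config List with entries:
#'   \describe{
#'     \item{design}{`"historical"`, `"agestage"` or `"simple"`.}
#'     \item{space}{A `state_space`.}
#'     \item{rates}{Named list per response; each entry a list with
#'       `terms` (term vector) and optionally `select = TRUE` plus
#'       `interactions` for exhaustive AICc selection over the reduced
#'       models of the global model.}
#'     \item{fec}{A [fecundity_params()].}
#'     \item{area}{Plot area (m^2).}
#'     \item{dd_rate}{Optional density-dependent rate name.}
#'     \item{plateau_target}{Optional target plateau density.}
#'     \item{backend}{Fit backend, `"ridge"` (default) or `"glmm"`.}
#'   }
#' @return A [sprout_model()]; fitted `vr_fit` objects are attached as
#'   attribute `fits`.
#' @export
fit_model_bundle <- function(table, climate, config) {
  specs <- list()
  fits <- list()
  backend <- config$backend %||% "ridge"
  for (r in names(config$rates)) {
    rc <- config$rates[[r]]
    des <- build_design(table, climate, config$design, r)
    fam <- resp_defs[[r]]$family
    if (isTRUE(rc$select)) {
      cand <- enumerate_reduced_models(rc$terms, rc$interactions %||% character())
      cfits <- lapply(cand, function(tm)
        tryCatch(fit_vital_rate(des, tm, family = fam, backend = backend,
                                truncated = isTRUE(rc$truncated)),
                 error = function(e) structure(list(converged = FALSE, terms = tm,
                                                    family = fam),
                                               class = "vr_fit")))
      fit <- select_model(cfits)
    } else {
      fit <- fit_vital_rate(des, rc$terms, family = fam, backend = backend,
                            truncated = isTRUE(rc$truncated))
      if (!fit$converged) ss_stop("fit_error", sprintf("'%s' fit failed to converge", r))
    }
    specs[[r]] <- fit$spec
    fits[[r]] <- fit
  }
  climate_spec <- config$climate_spec
  if (is.null(climate_spec)) {
    ## derive covariate means/sds from the series for every climate
    ## covariate any fitted spec references
    used <- unique(unlist(lapply(specs, function(s) terms_covariates(s$terms))))
    cc <- setdiff(grep("_(t|tp1|tm1)$", used, value = TRUE),
                  c("siz_t", "flwyn_t", "siz_tm1", "flwyn_tm1", "grw_t",
                    "age", "density", "siz_target", "flw_t"))
    mu <- sdv <- setNames(numeric(0), character(0))
    for (v in cc) {
      base <- sub("_(t|tp1|tm1)$", "", v)
      if (!is.null(climate) && base %in% climate_vars(climate)) {
        mu[v] <- mean(climate[[base]])
        sdv[v] <- sd(climate[[base]])
      }
    }
    climate_spec <- list(mean = mu, sd = sdv)
  }
  mdl <- sprout_model(config$space, specs, config$fec %||% fecundity_params(),
                      climate_spec = climate_spec,
                      area = config$area %||% 100,
                      dd_rate = config$dd_rate)
  attr(mdl, "fits") <- fits
  mdl
}

#' Write ESS / trajectory results as JSON and CSV
#'
#' @param est An `ess_estimate`.
#' @param path File path (`.json`).
#' @export
write_ess_json <- function(est, path) {
  jsonlite::write_json(unclass(est)[c("d_star", "gradient", "convergence_stable",
                                      "local_max", "se", "mode")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ess_json
#' @param trajectory An `evolution_trajectory`.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
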