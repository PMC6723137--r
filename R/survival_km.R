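#' Kaplan-Meier estimate of inbred-line survival
#'
#' Product-limit estimate of the probability that an inbred line is still
#' reproducing after a given number of selfing generations, from
#' right-censored line records (see [readLineRecords()]). Extinct lines
#' contribute an event at `generations_survived`; censored lines contribute
#' to risk sets only. Pointwise 95% confidence bands use the Greenwood
#' variance on the log(-log) scale. Computation is delegated to
#' [survival::survfit()].
#'
#' @param lines Line-record `data.frame` with columns `generations_survived`
#'   and `status` (`"extinct"` / `"censored"`).
#' @param conf Confidence level (default 0.95).
#' @return `data.frame` of class `c("survivalCurve", "data.frame")` with
#'   columns `time`, `n_risk`, `n_event`, `n_censor`, `surv`, `lower`,
#'   `upper`; `S(0) = 1` implicitly (times start at the first observed time).
#' @export
kmEstimate <- function(lines, conf = 0.95) {
  if (!nrow(lines)) stop("no line records")
  if (!all(c("generations_survived", "status") %in% colnames(lines))) {
    stop("line records need columns 'generations_survived' and 'status'")
  }
  ev <- as.integer(lines$status == "extinct")
  fit <- survival::survfit(
    survival::Surv(lines$generations_survived, ev) ~ 1,
    conf.type = "log-log", conf.int = conf
  )
  out <- data.frame(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    surv = fit$surv,
    lower = ifelse(is.na(fit$lower), fit$surv, fit$lower),
    upper = ifelse(is.na(fit$upper), fit$surv, fit$upper)
  )
  class(out) <- c("survivalCurve", "data.frame")
  out
}

#' Evaluate a survival curve at a time point
#'
#' Right-continuous step-function evaluation: returns 1 before the first
#' event time and the last estimate beyond the final time.
#'
#' @param curve Result of [kmEstimate()].
#' @param t Generation (>= 0); vectorized.
#' @return Survival probability estimate(s).
#' @export
survivalAt <- function(curve, t) {
  stopifnot(all(t >= 0))
  vapply(t, function(tt) {
    i <- which(curve$time <= tt)
    if (!length(i)) 1 else curve$surv[max(i)]
  }, numeric(1))
}
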