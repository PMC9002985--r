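#' Specify a mediation model
#'
#' Defines which line, outcome set and bronchodilator state a fit uses.
#' `outcomes = "pair"` analyses FEV1 and FVC jointly as correlated outcomes
#' (model 1); `outcomes = "ratio"` analyses 100 * FEV1/FVC as a single
#' outcome (model 2). Exposure enters as two dummies (`before_puberty`,
#' `at30_not_before`) against `never`; parent education confounds the
#' mediator and outcome equations; offspring age and smoking adjust the
#' outcome equations only.
#'
#' @param line `"paternal"` or `"maternal"`.
#' @param outcomes `"pair"` or `"ratio"`.
#' @param bronchodilator `"pre"` or `"post"`.
#' @param quadrature_order Gauss-Hermite order for
#'   [observed_loglik()]'s quadrature method; must be at least 11.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(line = "paternal", outcomes = c("pair", "ratio"),
                       bronchodilator = c("pre", "post"),
                       quadrature_order = 41) {
  line <- match.arg(line, LINE_LEVELS)
  outcomes <- match.arg(outcomes)
  bronchodilator <- match.arg(bronchodilator)
  if (quadrature_order < 11)
    abort("quadrature_order below 11 is not allowed")
  structure(
    list(line = line, outcomes = outcomes, bronchodilator = bronchodilator,
         quadrature_order = as.integer(quadrature_order)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> line=%s outcomes=%s bronchodilator=%s\n",
              x$line, x$outcomes, x$bronchodilator))
  invisible(x)
}

outcome_names <- function(spec) {
  if (spec$outcomes == "pair") c("fev1", "fvc") else "ratio"
}

# Assemble the numeric arrays the compiled likelihood consumes for one line.
# Rows with missing post-bronchodilator values are dropped (logged) when the
# spec asks for the post state.
build_model_frame <- function(data, spec) {
  data <- as_tibble(data)
  data <- filter(data, .data$line == spec$line)
  if (nrow(data) == 0) abort(paste0("no records for line '", spec$line, "'"))
  if (spec$bronchodilator == "post") {
    miss <- is.na(data$fev1_post_ml) | is.na(data$fvc_post_ml)
    drop_log("missing post-bronchodilator values", sum(miss))
    data <- data[!miss, ]
    if (nrow(data) == 0) abort("no post-bronchodilator records")
    fev1 <- data$fev1_post_ml; fvc <- data$fvc_post_ml
  } else {
    fev1 <- data$fev1_ml; fvc <- data$fvc_ml
  }
  W <- if (spec$outcomes == "pair") cbind(data$height_cm, fev1, fvc)
       else cbind(data$height_cm, 100 * fev1 / fvc)
  colnames(W) <- c("height_cm", outcome_names(spec))
  e1 <- as.numeric(data$parent_exposure == "before_puberty")
  e2 <- as.numeric(data$parent_exposure == "at30_not_before")
  edu <- as.numeric(data$parent_edu_low)
  X4 <- cbind(1, e1, e2, edu)
  X6 <- cbind(X4, data$age, as.numeric(data$ever_smoker))
  list(
    data = data,
    K = ncol(W) - 1L,
    X4 = X4, X6 = X6, W = W,
    m1 = as.integer(data$m1_overweight_prepuberty),
    group = as.integer(factor(as.character(data$sex), levels = SEX_LEVELS)),
    cluster = as.integer(factor(data$parent_id)),
    outcome_names = outcome_names(spec)
  )
}

frame_scaling <- function(frame) {
  K <- frame$K
  list(
    m_mu = mean(frame$W[, 1]), m_sd = sd(frame$W[, 1]),
    y_mu = colMeans(frame$W[, -1, drop = FALSE]),
    y_sd = apply(frame$W[, -1, drop = FALSE], 2, sd),
    age_mu = mean(frame$X6[, 5]), age_sd = sd(frame$X6[, 5])
  )
}

scale_frame <- function(frame, scaling) {
  s <- scaling
  Ws <- frame$W
  Ws[, 1] <- (Ws[, 1] - s$m_mu) / s$m_sd
  for (k in seq_len(frame$K))
    Ws[, k + 1] <- (Ws[, k + 1] - s$y_mu[k]) / s$y_sd[k]
  X6s <- frame$X6
  X6s[, 5] <- (X6s[, 5] - s$age_mu) / s$age_sd
  frame$W <- Ws; frame$X6 <- X6s
  frame
}
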