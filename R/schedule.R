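#' Build a session schedule
#'
#' Constructs the table of scanning sessions and their elapsed times for the
#' two dense-sampling designs the pipeline supports, or for a custom design.
#'
#' `"female30"` is one session per day for 30 consecutive days (elapsed times
#' 0, 1, ..., 29 days). `"male40"` is 40 sessions over the same 30 days:
#' morning scans on days 1-10, morning and evening scans on days 11-20, and
#' evening scans on days 21-30. Morning and evening scans are 13 hours apart
#' (07:00 and 20:00), encoded as a fractional day of 13/24.
#'
#' @param design One of `"female30"`, `"male40"`, or `"custom"`.
#' @param t_days For `design = "custom"`, a strictly increasing numeric vector
#'   of elapsed times in days; the first element must be 0.
#' @return A data frame with columns `session_id` (character) and `t_days`
#'   (numeric, days since the first session), with the design label stored in
#'   `attr(x, "design")`.
#' @examples
#' sch <- make_schedule("female30")
#' nrow(sch)        # 30
#' range(sch$t_days)
#' @export
make_schedule <- function(design = c("female30", "male40", "custom"),
                          t_days = NULL) {
  if (!is.character(design) || length(design) != 1L ||
      !design %in% c("female30", "male40", "custom"))
    stop_config("unknown schedule design %s; expected 'female30', 'male40' or 'custom'",
                deparse(substitute(design)))

  pm <- 13 / 24  # 07:00 -> 20:00 same day
  t <- switch(design,
    female30 = as.numeric(0:29),
    male40 = {
      am_only <- 0:9
      both    <- as.vector(rbind(10:19, 10:19 + pm))
      pm_only <- 20:29 + pm
      c(am_only, both, pm_only)
    },
    custom = {
      if (is.null(t_days) || !is.numeric(t_days) || length(t_days) < 1L)
        stop_config("custom design requires a numeric t_days vector")
      as.numeric(t_days)
    })

  if (t[1] != 0)
    stop_config("schedule must start at t = 0 (got %g)", t[1])
  if (length(t) > 1L && any(diff(t) <= 0))
    stop_config("schedule times must be strictly increasing")

  out <- data.frame(
    session_id = sprintf("ses-%02d", seq_along(t)),
    t_days = t,
    stringsAsFactors = FALSE
  )
  attr(out, "design") <- design
  out
}
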