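# JSON serialisation of task conditions. Two fixture configs ship with the
# package: part1.json (sigma = 1 cm) and part2.json (sigma = 4 cm).

#' Read / write a task condition as JSON
#'
#' Schema: `{"prior_m1": [{"w":, "mu":, "var":}, ...], "prior_m2": [...],
#' "p_m1": 0.5, "d_max": 8, "probe_widths": [3, 5, 8]}`. The shipped fixture
#' configs can be read with e.g.
#' `read_task_condition(system.file("extdata", "part1.json",
#' package = "shiftselect"))`.
#'
#' @param file Path to a JSON file.
#' @param cond A [task_condition()].
#' @return `read_task_condition()` returns a `task_condition`;
#'   `write_task_condition()` returns `file` invisibly.
#' @export
read_task_condition <- function(file) {
  x <- jsonlite::fromJSON(file, simplifyDataFrame = TRUE)
  need <- c("prior_m1", "prior_m2", "p_m1", "d_max", "probe_widths")
  if (!all(need %in% names(x)))
    stop("condition JSON must contain fields: ", paste(need, collapse = ", "))
  as_prior <- function(df) shift_prior(df$w, df$mu, df$var)
  task_condition(prior_m1 = as_prior(x$prior_m1),
                 prior_m2 = as_prior(x$prior_m2),
                 p_m1 = x$p_m1, d_max = x$d_max,
                 probe_widths = x$probe_widths)
}

#' @rdname read_task_condition
#' @export
write_task_condition <- function(cond, file) {
  stopifnot(inherits(cond, "task_condition"))
  as_df <- function(p) data.frame(w = p$weights, mu = p$means, var = p$vars)
  jsonlite::write_json(list(prior_m1 = as_df(cond$prior_m1),
                            prior_m2 = as_df(cond$prior_m2),
                            p_m1 = cond$p_m1, d_max = cond$d_max,
                            probe_widths = cond$probe_widths),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
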