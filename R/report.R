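# Console-level front end: the four analysis entry points behind the CLI
# subcommands, each writing machine-readable outputs plus a run record
# (all inputs, seed and package version) from which the run can be
# reproduced exactly.  Probabilities are shown to 2 decimals in
# human-readable output and kept at full precision in files.

write_run_record <- function(out_dir, subcommand, params) {
  record <- list(subcommand = subcommand, params = params,
                 package = "ph2select",
                 version = as.character(packageVersion("ph2select")))
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

write_table <- function(df, out_dir, stem, format) {
  path <- file.path(out_dir, paste0(stem, ".", format))
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  path
}

#' Protocol text for the decision rule
#'
#' Renders a plain-text paragraph, suitable for a protocol or statistical
#' analysis plan, stating the decision rule and the inputs in force.
#'
#' @param criteria A `posterior_criteria` object.
#' @param n_a,s_a,n_b,s_b Per-arm sample sizes and responder counts.
#' @param prior_a,prior_b The [beta_params] priors used.
#' @return A character string.
#' @export
sap_text <- function(criteria, n_a, s_a, n_b, s_b, prior_a, prior_b) {
  sprintf(paste0(
    "The response rate on each arm is assigned a Beta prior: ",
    "Beta(%g, %g) on arm A and Beta(%g, %g) on arm B. After observing ",
    "%d responders among %d patients on arm A and %d responders among ",
    "%d patients on arm B, the posterior probability that arm A's rate ",
    "exceeds arm B's by more than the clinically meaningful difference ",
    "d = %g is PCorr* = %.2f, and the posterior probability that the two ",
    "rates differ by at most d is PAmb* = %.2f. The decision criterion ",
    "lambda* = PCorr* + %g x PAmb* = %.2f. Arm A is selected outright if ",
    "lambda* exceeds the pre-specified threshold theta = %g; otherwise ",
    "the selection between arms is based on secondary factors such as ",
    "safety, cost and ease of administration. Here lambda* %s theta, so ",
    "the recommendation is: %s."),
    prior_a$alpha, prior_a$beta, prior_b$alpha, prior_b$beta,
    s_a, n_a, s_b, n_b, criteria$d, criteria$p_correct,
    criteria$p_ambiguous, criteria$rho, criteria$lambda_star,
    criteria$theta,
    if (criteria$decision == "SELECT_A") "exceeds" else "does not exceed",
    if (criteria$decision == "SELECT_A") "select arm A"
    else "consider other factors for choosing between arms A and B")
}

#' Post-trial analysis report
#'
#' Updates the priors with the observed per-arm counts, computes the
#' posterior criteria and the threshold decision, and (optionally)
#' writes the results, a protocol-style text paragraph and a run record
#' to `out_dir`.
#'
#' @param alpha_a,beta_a,alpha_b,beta_b Prior parameters per arm.
#' @param n_a,s_a,n_b,s_b Observed patients and responders per arm.
#' @param d,rho,theta Decision constants (see [design_params]).
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param format `"json"` or `"csv"` for the results table.
#' @return A list of class `ph2_report` with elements `criteria`,
#'   `decision`, `sap`, `table` and `files`.
#' @examples
#' rep <- run_evaluate(n_a = 40, s_a = 22, n_b = 40, s_b = 16,
#'                     d = 0.10, rho = 0.5, theta = 0.90)
#' rep$criteria
#' @export
run_evaluate <- function(alpha_a = 1, beta_a = 1, alpha_b = 1, beta_b = 1,
                         n_a, s_a, n_b, s_b, d, rho, theta = 0.90,
                         out_dir = NULL, format = c("json", "csv")) {
  format <- match.arg(format)
  prior_a <- beta_params(alpha_a, beta_a)
  prior_b <- beta_params(alpha_b, beta_b)
  params <- design_params(d = d, rho = rho, theta = theta)
  post_a <- beta_update(prior_a, arm_outcome(n_a, s_a))
  post_b <- beta_update(prior_b, arm_outcome(n_b, s_b))
  crit <- lambda_star(post_a, post_b, params)
  tab <- data.frame(p_correct = crit$p_correct,
                    p_ambiguous = crit$p_ambiguous,
                    lambda_star = crit$lambda_star,
                    decision = crit$decision)
  sap <- sap_text(crit, n_a, s_a, n_b, s_b, prior_a, prior_b)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_table(tab, out_dir, "evaluate", format)
    sap_path <- file.path(out_dir, "sap.txt")
    writeLines(sap, sap_path)
    write_run_record(out_dir, "evaluate",
                     list(alpha_a = alpha_a, beta_a = beta_a,
                          alpha_b = alpha_b, beta_b = beta_b,
                          n_a = n_a, s_a = s_a, n_b = n_b, s_b = s_b,
                          d = d, rho = rho, theta = theta, format = format))
    files <- c(files, sap_path, file.path(out_dir, "run_record.json"))
  }
  structure(list(criteria = crit, decision = crit$decision, sap = sap,
                 table = tab, files = files),
            class = "ph2_report")
}

#' @export
print.ph2_report <- function(x, ...) {
  if (!is.null(x$criteria)) print(x$criteria)
  if (!is.null(x$results)) for (r in x$results) print(r)
  if (is.null(x$criteria) && is.null(x$results) && !is.null(x$table)) {
    tab <- x$table
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(v)
      ifelse(abs(v - round(v)) < .Machine$double.eps^0.5, v, round(v, 2)))
    print(tab, row.names = FALSE)
  }
  if (!is.null(x$sap)) cat("\n", strwrap(x$sap, width = 72), sep = "\n")
  invisible(x)
}

#' Sample-size report
#'
#' Runs the deterministic and/or simulation-based search and writes the
#' minimal sample sizes together with the criterion traces.
#'
#' @param pi_a,pi_b Anticipated response rates (`pi_a > pi_b`).
#' @param alpha_a,beta_a,alpha_b,beta_b Prior parameters per arm.
#' @param d,rho Decision constants.
#' @param gamma Design-stage threshold `gamma*`.
#' @param method `"deterministic"`, `"simulated"` (Monte Carlo
#'   `lambda-bar*`), `"exact"` (enumerated `lambda-bar*`) or `"both"`
#'   (deterministic + exact).
#' @param m Monte Carlo replicates for `method = "simulated"`.
#' @param n_max Upper end of the per-group search range.
#' @param seed Root seed for the Monte Carlo search.
#' @param out_dir,format As in [run_evaluate].
#' @return A `ph2_report` whose `results` element is a named list of
#'   `sample_size_result` objects and whose `table` summarises them
#'   (`n_min` is the true integer; displays mask values under 10 as
#'   `"<10"`).
#' @export
run_design <- function(pi_a, pi_b, alpha_a = 1, beta_a = 1,
                       alpha_b = 1, beta_b = 1, d, rho, gamma,
                       method = c("deterministic", "simulated", "exact",
                                  "both"),
                       m = 10000L, n_max = 1000L, seed = 1L,
                       out_dir = NULL, format = c("json", "csv")) {
  method <- match.arg(method)
  format <- match.arg(format)
  req <- ss_request(pi_a, pi_b, beta_params(alpha_a, beta_a),
                    beta_params(alpha_b, beta_b), d = d, rho = rho,
                    gamma_star = gamma, n_max_search = n_max, m = m,
                    seed = seed)
  results <- list()
  if (method %in% c("deterministic", "both"))
    results$deterministic <- find_nmin_deterministic(req)
  if (method == "simulated")
    results$simulated <- find_nmin_simulated(req, method = "mc")
  if (method %in% c("exact", "both"))
    results$exact <- find_nmin_simulated(req, method = "exact")
  tab <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(method = r$method, gamma_star = r$gamma_star,
               n_min = r$n_min, found = r$found,
               max_criterion = max(r$trace$criterion))
  }))
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_table(tab, out_dir, "design", format)
    for (nm in names(results)) {
      p <- file.path(out_dir, paste0("trace_", nm, ".csv"))
      write_trace_csv(results[[nm]], p)
      files <- c(files, p)
    }
    write_run_record(out_dir, "design",
                     list(pi_a = pi_a, pi_b = pi_b, alpha_a = alpha_a,
                          beta_a = beta_a, alpha_b = alpha_b,
                          beta_b = beta_b, d = d, rho = rho, gamma = gamma,
                          method = method, m = m, n_max = n_max,
                          seed = seed, format = format))
    files <- c(files, file.path(out_dir, "run_record.json"))
  }
  structure(list(results = results, table = tab, files = files),
            class = "ph2_report")
}

#' Operating-characteristics report
#'
#' Evaluates one scenario or a list of scenarios and writes the tidy
#' grid table.
#'
#' @param scenarios A list of [oc_scenario] objects.
#' @param backend `"mc"` (the design's reference procedure) or
#'   `"exact"`.
#' @param out_dir,format As in [run_evaluate].
#' @return A `ph2_report` whose `table` is the [oc_grid] data.frame.
#' @export
run_oc <- function(scenarios, backend = c("mc", "exact"),
                   out_dir = NULL, format = c("json", "csv")) {
  backend <- match.arg(backend)
  format <- match.arg(format)
  tab <- oc_grid(scenarios, backend = backend)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_table(tab, out_dir, "oc", format)
    write_run_record(out_dir, "oc",
                     list(backend = backend, format = format,
                          scenarios = lapply(scenarios, function(s)
                            list(true_pi_a = s$true_pi_a,
                                 true_pi_b = s$true_pi_b,
                                 alpha_a = s$prior_a$alpha,
                                 beta_a = s$prior_a$beta,
                                 alpha_b = s$prior_b$alpha,
                                 beta_b = s$prior_b$beta,
                                 n_per_arm = s$n_per_arm, d = s$d,
                                 rho = s$rho, theta = s$theta, k = s$k,
                                 seed = s$seed))))
    files <- c(files, file.path(out_dir, "run_record.json"))
  }
  structure(list(table = tab, files = files), class = "ph2_report")
}

#' Frequentist-versus-Bayesian comparison report
#'
#' Computes the exact Sargent-Goldberg `lambda` at `n` per group next to
#' the Bayesian `lambda*` obtained from the same inputs (vague-prior
#' update with the expected responder counts), and optionally the
#' frequentist required sample size at a threshold.
#'
#' @param pi_a,pi_b True response rates (`pi_a > pi_b`).
#' @param d,rho Decision constants.
#' @param n Per-group sample size for the criterion comparison (optional
#'   when `threshold` is given).
#' @param threshold Required `lambda` for the sample-size search
#'   (optional when `n` is given).
#' @param alpha_a,beta_a,alpha_b,beta_b Priors for the Bayesian side.
#' @param n_max Upper end of the search range.
#' @param out_dir,format As in [run_evaluate].
#' @return A `ph2_report` with a one-row comparison `table` and, when
#'   `threshold` is given, the `sg_n` search result.
#' @export
run_sg <- function(pi_a, pi_b, d, rho = 0.5, n = NULL, threshold = NULL,
                   alpha_a = 1, beta_a = 1, alpha_b = 1, beta_b = 1,
                   n_max = 1000L, out_dir = NULL,
                   format = c("json", "csv")) {
  format <- match.arg(format)
  if (is.null(n) && is.null(threshold))
    stop("supply 'n' (criterion comparison) and/or 'threshold' ",
         "(sample-size search)", call. = FALSE)
  lam_sg <- lam_bayes <- NA_real_
  if (!is.null(n)) {
    lam_sg <- sg_lambda(sg_scenario(pi_a, pi_b, d, rho, n))
    req <- ss_request(pi_a, pi_b, beta_params(alpha_a, beta_a),
                      beta_params(alpha_b, beta_b), d = d, rho = rho,
                      gamma_star = 0.5, n_max_search = max(n, 2L))
    lam_bayes <- lambda_at_n(req, n)
  }
  sg_n <- NULL
  if (!is.null(threshold))
    sg_n <- sg_sample_size(pi_a, pi_b, d, rho, threshold,
                           n_max_search = n_max)
  tab <- data.frame(pi_a = pi_a, pi_b = pi_b, d = d, rho = rho,
                    n = if (is.null(n)) NA_integer_ else n,
                    sg_lambda = lam_sg, bayes_lambda_star = lam_bayes,
                    sg_threshold = if (is.null(threshold)) NA_real_
                                   else threshold,
                    sg_n_min = if (is.null(sg_n)) NA_integer_
                               else sg_n$n_min)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_table(tab, out_dir, "sg", format)
    if (!is.null(sg_n)) {
      p <- file.path(out_dir, "trace_sg.csv")
      write_trace_csv(sg_n, p)
      files <- c(files, p)
    }
    write_run_record(out_dir, "sg",
                     list(pi_a = pi_a, pi_b = pi_b, d = d, rho = rho,
                          n = n, threshold = threshold,
                          alpha_a = alpha_a, beta_a = beta_a,
                          alpha_b = alpha_b, beta_b = beta_b,
                          n_max = n_max, format = format))
    files <- c(files, file.path(out_dir, "run_record.json"))
  }
  structure(list(table = tab, sg_n = sg_n, files = files),
            class = "ph2_report")
}

#' Re-run an analysis from its run record
#'
#' Reads the `run_record.json` written alongside any report and repeats
#' the run with identical inputs, so outputs are reproduced exactly.
#'
#' @param record_path Path to a `run_record.json`.
#' @param out_dir Output directory for the reproduced run.
#' @return The reproduced `ph2_report`.
#' @export
run_from_record <- function(record_path, out_dir = NULL) {
  rec <- jsonlite::read_json(record_path, simplifyVector = TRUE)
  p <- as.list(rec$params)
  switch(rec$subcommand,
    evaluate = do.call(run_evaluate, c(p, list(out_dir = out_dir))),
    design = do.call(run_design, c(p, list(out_dir = out_dir))),
    sg = {
      p$n <- if (is.null(p$n) || all(is.na(p$n))) NULL else p$n
      p$threshold <- if (is.null(p$threshold) || all(is.na(p$threshold)))
        NULL else p$threshold
      do.call(run_sg, c(p, list(out_dir = out_dir)))
    },
    oc = {
      scen <- lapply(seq_len(nrow(p$scenarios)), function(i) {
        s <- p$scenarios[i, ]
        oc_scenario(s$true_pi_a, s$true_pi_b,
                    beta_params(s$alpha_a, s$beta_a),
                    beta_params(s$alpha_b, s$beta_b),
                    n_per_arm = s$n_per_arm, d = s$d, rho = s$rho,
                    theta = s$theta, k = s$k, seed = s$seed)
      })
      run_oc(scen, backend = p$backend, out_dir = out_dir,
             format = p$format)
    },
    stop("unknown subcommand in record: ", rec$subcommand, call. = FALSE))
}
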