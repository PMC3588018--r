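#' Load a run configuration from a YAML file
#'
#' The configuration mirrors the model inputs in user units, grouped into
#' blocks:
#'
#' ```yaml
#' parameters:            # K, nm^2, nm, Debye, mol/l; all optional
#'   T: 310
#'   a0: 0.48
#'   D: 0.42
#'   p0: 3.1
#'   salt: 0.1
#'   water: 55
#'   n_refr: 1.33
#'   alpha: 0.5           # optional: lattice headgroup statistics
#'   L: 12
#' solver:
#'   nodes: 4000
#'   damping: 0.25
#'   tol: 1.0e-9
#'   max_iter: 10000
#' output:
#'   dir: "."
#' sweep:
#'   t_list: [300, 310, 318, 323]
#' alphas: [0.1, 1, 10]
#' ```
#'
#' Missing fields take the DPPC gel-phase defaults; unknown keys are
#' rejected by name so typos cannot silently fall back to defaults.
#'
#' @param path YAML file, or `NULL` for the full default configuration.
#' @return Object of class `mlpb_config`: list with `params`
#'   ([mlpb_parameters()]), `opts` ([solver_options()]), `nodes`, `output`,
#'   `sweep`, `alphas`, and the `resolved` user-unit parameter list (the
#'   exact values a rerun needs).
#' @export
load_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    out <- tryCatch(yaml::read_yaml(path), error = function(e)
      stop("cannot parse config '", path, "': ", conditionMessage(e),
           call. = FALSE))
    if (is.null(out)) list() else out
  }
  known_blocks <- c("parameters", "solver", "output", "sweep", "alphas")
  bad <- setdiff(names(cfg), known_blocks)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)

  par_defaults <- list(T = 310, a0 = 0.48, D = 0.42, p0 = 3.1, salt = 0.1,
                       water = 55, n_refr = 1.33, alpha = NULL, L = 12)
  pb <- cfg$parameters
  bad <- setdiff(names(pb), names(par_defaults))
  if (length(bad))
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  pars <- utils::modifyList(par_defaults, as.list(pb))

  sol_defaults <- list(nodes = 4000, damping = 0.25, tol = 1e-9,
                       max_iter = 10000)
  sb <- cfg$solver
  bad <- setdiff(names(sb), names(sol_defaults))
  if (length(bad))
    stop("unknown solver key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  sol <- utils::modifyList(sol_defaults, as.list(sb))

  ob <- cfg$output
  bad <- setdiff(names(ob), "dir")
  if (length(bad))
    stop("unknown output key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  sw <- cfg$sweep
  bad <- setdiff(names(sw), "t_list")
  if (length(bad))
    stop("unknown sweep key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  params <- do.call(mlpb_parameters, pars)
  structure(list(
    params = params,
    opts = solver_options(max_iter = sol$max_iter, damping = sol$damping,
                          tol = sol$tol),
    nodes = sol$nodes,
    output = list(dir = if (is.null(ob$dir)) "." else ob$dir),
    sweep = if (is.null(sw$t_list)) NULL else as.numeric(sw$t_list),
    alphas = if (is.null(cfg$alphas)) NULL else as.numeric(cfg$alphas),
    resolved = pars
  ), class = "mlpb_config")
}

#' Write profile table and run summary
#'
#' Writes the profiles as a tab-delimited text table in user units with a
#' fixed column schema (`x_nm`, `phi_mV`, `eps_r`, `n_plus_mol_per_l`,
#' `n_minus_mol_per_l`, `rho_ions_C_per_m3`, `rho_zw_C_per_m3`,
#' `prob_density`), 12 significant digits, plus a YAML run summary
#' (`<path>.summary.yaml`) holding the resolved configuration, convergence
#' record, and scalar observables — everything needed to rerun the case.
#'
#' @param profiles an [extract_profiles()] object.
#' @param path output file path for the table.
#' @param summary optional named list merged into the summary document.
#' @return Invisibly, the summary list.
#' @export
write_profiles <- function(profiles, path, summary = list()) {
  stopifnot(inherits(profiles, "mlpb_profiles"))
  params <- attr(profiles, "params")
  mol <- 1e3 * mlpb_constants()$N_A
  tab <- data.frame(
    x_nm = profiles$x * 1e9,
    phi_mV = profiles$phi * 1e3,
    eps_r = profiles$eps_r,
    n_plus_mol_per_l = profiles$n_plus / mol,
    n_minus_mol_per_l = profiles$n_minus / mol,
    rho_ions_C_per_m3 = profiles$rho_ions,
    rho_zw_C_per_m3 = profiles$rho_zw,
    prob_density = profiles$prob_density
  )
  fmt <- vapply(tab, function(col) format(col, digits = 12, trim = TRUE,
                                          scientific = NA),
                character(nrow(tab)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = "\t"), con)
  utils::write.table(fmt, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  info <- c(list(
    package_version = as.character(utils::packageVersion("mlpb")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(
      T = params$T, a0_nm2 = params$a0 * 1e18, D_nm = params$D * 1e9,
      p0_debye = params$p0 / mlpb_constants()$debye,
      salt_mol_l = params$n0 / mol, water_mol_l = params$n0w / mol,
      n_refr = params$n_refr,
      alpha = if (is.null(params$alpha)) "none" else params$alpha,
      L_nm = params$L * 1e9),
    convergence = list(iterations = attr(profiles, "iterations"),
                       final_residual_V = attr(profiles, "residual")),
    results = list(
      phi_surface_mV = profiles$phi[1] * 1e3,
      eps_surface = profiles$eps_r[1],
      eps_far = profiles$eps_r[nrow(profiles)],
      lambda = attr(profiles, "lambda"))
  ), summary)
  yaml::write_yaml(info, paste0(path, ".summary.yaml"))
  invisible(info)
}

#' Command-line driver
#'
#' Implements the `mlpb` command (see `exec/mlpb`). Subcommands:
#'
#' * `solve`: run one boundary-value solve, write `profiles.tsv` (plus its
#'   summary) to the output directory;
#' * `sweep`: temperature sweep, write `sweep.tsv`;
#' * `probability`: probability-density curve family over `--alpha` values,
#'   write `probability.tsv`.
#'
#' Flags: `--preset dppc-gel|dppc-liquid`, `--config FILE`, `--t K`,
#' `--a0 NM2`, `--d NM`, `--p0 DEBYE`, `--salt MOL_L`, `--alpha X[,X...]`,
#' `--t-list K,K,...`, `--nodes N`, `--out DIR`. Command-line flags override
#' config values, which override the DPPC gel defaults.
#'
#' @param argv character vector of command-line arguments.
#' @return Exit status, invisibly: 0 on success, 1 on user/convergence
#'   error, 2 on usage error.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mlpb <solve|sweep|probability> [--preset NAME] [--config FILE]",
    "            [--t K] [--a0 NM2] [--d NM] [--p0 DEBYE] [--salt MOL_L]",
    "            [--alpha X[,X...]] [--t-list K,K,...] [--nodes N] [--out DIR]",
    sep = "\n")
  if (length(argv) < 1L || argv[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(if (length(argv) < 1L) 2L else 0L))
  }
  cmd <- argv[1]
  if (!cmd %in% c("solve", "sweep", "probability")) {
    message("unknown subcommand '", cmd, "'\n", usage)
    return(invisible(2L))
  }
  status <- tryCatch({
    flags <- .parse_flags(argv[-1])
    cfg <- load_config(flags$config)
    pars <- cfg$resolved
    if (!is.null(flags$preset)) {
      pp <- if (flags$preset == "dppc-gel") list(T = 310, a0 = 0.48)
      else if (flags$preset == "dppc-liquid") list(T = 323, a0 = 0.60)
      else stop("unknown preset '", flags$preset, "'", call. = FALSE)
      pars <- utils::modifyList(pars, pp)
    }
    for (k in c("t", "a0", "d", "p0", "salt")) {
      if (!is.null(flags[[k]])) {
        key <- c(t = "T", a0 = "a0", d = "D", p0 = "p0", salt = "salt")[[k]]
        pars[[key]] <- as.numeric(flags[[k]])
      }
    }
    if (!is.null(flags$t) && is.null(flags$a0) && is.null(flags$preset))
      pars$a0 <- dppc_phase_area(pars$T)  # rejects the 314 K transition gap
    alphas <- if (!is.null(flags$alpha))
      as.numeric(strsplit(flags$alpha, ",")[[1]]) else cfg$alphas
    nodes <- if (!is.null(flags$nodes)) as.integer(flags$nodes) else cfg$nodes
    out_dir <- if (!is.null(flags$out)) flags$out else cfg$output$dir
    if (!dir.exists(out_dir))
      dir.create(out_dir, recursive = TRUE)

    if (cmd == "sweep") {
      t_list <- if (!is.null(flags$`t-list`))
        as.numeric(strsplit(flags$`t-list`, ",")[[1]]) else cfg$sweep
      if (is.null(t_list))
        stop("sweep needs --t-list or a sweep block in the config",
             call. = FALSE)
      base <- do.call(mlpb_parameters,
                      utils::modifyList(pars, list(T = 310, a0 = 0.48)))
      sw <- temperature_sweep(base, t_list, n_nodes = nodes, opts = cfg$opts)
      fp <- file.path(out_dir, "sweep.tsv")
      utils::write.table(format(as.data.frame(sw), digits = 12),
                         fp, sep = "\t", quote = FALSE, row.names = FALSE)
      message("wrote ", fp)
      return(invisible(0L))
    }

    params <- do.call(mlpb_parameters, pars)
    sol <- solve_mlpb(params, grid = build_grid(params, nodes),
                      opts = cfg$opts)
    message(sprintf("converged in %d sweeps, final residual %.2e V",
                    sol$iterations, sol$residual))
    if (cmd == "solve") {
      prof <- extract_profiles(sol)
      fp <- file.path(out_dir, "profiles.tsv")
      write_profiles(prof, fp,
                     summary = list(omega_deg =
                                      average_orientation_angle(sol)))
      message(sprintf("phi(0) = %.2f mV, eps_r(0) = %.2f",
                      sol$phi[1] * 1e3, sol$eps_r[1]))
      message("wrote ", fp, " and ", fp, ".summary.yaml")
    } else {  # probability
      if (is.null(alphas))
        stop("probability needs --alpha or an alphas list in the config",
             call. = FALSE)
      fam <- probability_density_comparison(sol, alphas)
      fam$x_nm <- fam$x * 1e9
      fp <- file.path(out_dir, "probability.tsv")
      utils::write.table(
        format(fam[c("x_nm", "curve", "alpha", "prob_density")],
               digits = 12),
        fp, sep = "\t", quote = FALSE, row.names = FALSE)
      message("wrote ", fp)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument '", a, "'", call. = FALSE)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("flag --", key, " needs a value", call. = FALSE)
    flags[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  known <- c("preset", "config", "t", "a0", "d", "p0", "salt", "alpha",
             "t-list", "nodes", "out")
  bad <- setdiff(names(flags), known)
  if (length(bad))
    stop("unknown flag(s): ", paste0("--", bad, collapse = ", "),
         call. = FALSE)
  flags
}
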