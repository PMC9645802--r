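#' Model configuration as JSON
#'
#' The package's structured config format: a JSON document with `species`,
#' `reactions`, `diffusion`, `channels`, `membranes`, `initial`,
#' `injections`, scalar settings (`resistivity`, `temperature`,
#' `fixed_voltage`) and an optional `run` block (`t_end`, `efield_dt`,
#' `alpha_rd`, `record_dt`, `seed`, `ranks`, `probes`).  Voltage-dependent
#' channel rates are expressed either as numbers, as names of built-in rate
#' functions (the Hodgkin-Huxley alpha/beta family, see [hh_rates]), as
#' `{"table": {"v": [...], "rate": [...]}}` pairs interpolated linearly, or
#' whole channels as the preset `{"preset": "hh", "g_single": ...}`.
#' Arbitrary code is not accepted.
#'
#' @param path path to a JSON config.
#' @return `model_from_json`: a list with `model` (a [sim_model()]) and
#'   `run` (the run block, possibly `NULL`).
#' @export
model_from_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x, default = NULL) if (is.null(x)) default else as.numeric(x)
  sp <- if (length(cfg$species)) data.frame(
    name = vapply(cfg$species, function(s)
      if (is.list(s)) s$name else as.character(s), character(1)),
    valence = vapply(cfg$species, function(s)
      if (is.list(s)) num(s$valence, 0) else 0, numeric(1))
  ) else character(0)

  stoich <- function(x) {
    if (is.null(x) || !length(x)) return(c())
    stats::setNames(as.numeric(unlist(x)), names(x))
  }
  rxns <- lapply(cfg$reactions, function(r) {
    kind <- r$kind %||% "volume"
    switch(kind,
      volume = reaction(stoich(r$lhs), stoich(r$rhs), num(r$rate),
                        r$unit %||% "per_s", r$compartment %||% "comp"),
      surface = surface_reaction(stoich(r$lhs_tet), stoich(r$lhs_tri),
                                 stoich(r$rhs_tet), stoich(r$rhs_tri),
                                 rate = num(r$rate), unit = r$unit %||% "per_s",
                                 patch = r$patch),
      ghk = ghk_flux(r$species, r$patch, num(r$permeability),
                     num(r$outer_conc), num(r$channels, 1)),
      stop("unknown reaction kind: ", kind, call. = FALSE))
  })
  diff <- lapply(cfg$diffusion, function(d)
    diffusion_rule(d$species, num(d$D), d$compartment %||% "comp"))

  parse_rate <- function(r) {
    if (is.numeric(r) || (is.character(r) && !is.na(suppressWarnings(as.numeric(r))))) {
      return(as.numeric(r))
    }
    if (is.character(r)) {
      fn <- rate_builtins()[[r]]
      if (is.null(fn)) stop("unknown built-in rate function: ", r, call. = FALSE)
      return(fn)
    }
    if (is.list(r) && !is.null(r$table)) {
      v <- as.numeric(unlist(r$table$v)); rt <- as.numeric(unlist(r$table$rate))
      force(v); force(rt)
      return(function(V) stats::approx(v, rt, V, rule = 2)$y)
    }
    if (is.list(r) && !is.null(r$builtin)) {
      fn <- rate_builtins()[[r$builtin]]
      if (is.null(fn)) stop("unknown built-in rate function: ", r$builtin,
                            call. = FALSE)
      mult <- num(r$mult, 1)
      return(scaled_rate(fn, mult))
    }
    stop("cannot parse rate declaration", call. = FALSE)
  }
  chans <- list()
  for (ch in cfg$channels) {
    if (!is.null(ch$preset)) {
      if (ch$preset != "hh") stop("unknown channel preset: ", ch$preset,
                                  call. = FALSE)
      hh <- hh_gating_model(g_single = num(ch$g_single, 4e-12),
                            v_init = num(ch$v_init, -0.065))
      chans <- c(chans, unname(hh))
    } else {
      trans <- lapply(ch$transitions, function(tr)
        list(from = tr$from, to = tr$to, rate = parse_rate(tr$rate)))
      chans[[length(chans) + 1L]] <- channel(
        ch$name, unlist(ch$states), trans,
        open_states = unlist(ch$open_states) %||% character(0),
        g_single = num(ch$g_single, 0), reversal = num(ch$reversal, 0),
        initial = if (!is.null(ch$initial)) stoich(ch$initial) else NULL)
    }
  }
  membs <- lapply(cfg$membranes, function(m)
    membrane(m$patch, num(m$capacitance), num(m$leak, 0),
             num(m$leak_reversal, 0),
             channel_densities = stoich(m$channel_densities)))
  init <- lapply(cfg$initial, stoich)
  injs <- lapply(cfg$injections, function(j)
    list(at = if (!is.null(j$at)) as.numeric(unlist(j$at)),
         vertices = if (!is.null(j$vertices)) as.integer(unlist(j$vertices)),
         current = num(j$current)))

  model <- sim_model(
    species = sp, reactions = rxns, diffusion = diff, channels = chans,
    membranes = membs, initial = init, injections = injs,
    fixed_voltage = num(cfg$fixed_voltage),
    resistivity = num(cfg$resistivity, 1.0),
    temperature = num(cfg$temperature, DEFAULT_TEMPERATURE)
  )
  list(model = model, run = cfg$run)
}

#' @rdname model_from_json
#' @param model a [sim_model()].
#' @param run optional run block to embed.
#' @export
model_to_json <- function(model, path, run = NULL) {
  jsonlite::write_json(c(serialize_model(model),
                         if (!is.null(run)) list(run = run)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

# Model as plain JSON-able data.  Channel rate functions are re-expressed
# as built-in names where recognizable; otherwise serialization errors
# (configs cannot carry arbitrary code).
serialize_model <- function(model) {
  builtin_names <- names(rate_builtins())
  builtins <- rate_builtins()
  ser_rate <- function(r) {
    if (is.numeric(r)) return(r)
    for (nm in builtin_names) if (identical(r, builtins[[nm]])) return(nm)
    env <- environment(r)
    if (!is.null(env) && all(c("fn", "mult") %in% ls(env))) {
      fn <- get("fn", env)
      for (nm in builtin_names) {
        if (identical(fn, builtins[[nm]])) {
          return(list(builtin = nm, mult = get("mult", env)))
        }
      }
    }
    stop("channel rate function is not a serializable built-in", call. = FALSE)
  }
  list(
    species = lapply(seq_len(nrow(model$species)), function(i)
      list(name = model$species$name[i], valence = model$species$valence[i])),
    reactions = lapply(model$reactions, function(r) {
      out <- unclass(r)
      lapply(out, function(x) if (is.numeric(x) && !is.null(names(x)))
        as.list(x) else x)
    }),
    diffusion = lapply(model$diffusion, unclass),
    channels = lapply(model$channels, function(ch) list(
      name = ch$name, states = ch$states,
      transitions = lapply(ch$transitions, function(tr)
        list(from = tr$from, to = tr$to, rate = ser_rate(tr$rate))),
      open_states = ch$open_states, g_single = ch$g_single,
      reversal = ch$reversal, initial = as.list(ch$initial))),
    membranes = lapply(model$membranes, function(m) list(
      patch = m$patch, capacitance = m$capacitance, leak = m$leak,
      leak_reversal = m$leak_reversal,
      channel_densities = as.list(m$channel_densities))),
    initial = lapply(model$initial, as.list),
    injections = model$injections,
    fixed_voltage = model$fixed_voltage,
    resistivity = model$resistivity,
    temperature = model$temperature
  )
}
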