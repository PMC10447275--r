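#' @title Unit normalization
#' @description Internal unit system is {cm, mL, s, ng}. Every model equation
#'   is evaluated in that system; the I/O layer converts printed units (e.g.
#'   "4.2 uL/min") on the way in and renders them back on the way out.
#'   Tissue densities are taken as 1 g/mL throughout, so ng/g and ng/mL are
#'   interchangeable.
#' @name units
NULL

# quantity kind of each recognized parameter key
.ocupk_key_kinds <- c(
  V_t = "volume", V_Vit = "volume", V_ScCh = "volume", V_Ret = "volume",
  V_Aq = "volume",
  A_Globe = "area", A_Palp = "area", A_Bulb = "area", A_Cornea = "area",
  A_SCL = "area",
  Q_UvSc = "flow", Q_Vit_Aq = "flow", Q_Aq = "flow", Q_Drain = "flow",
  Clearance_ScCh = "flow",
  K_t = "dimensionless", K_Aq = "dimensionless", K_Vit = "dimensionless",
  K_ScCh = "dimensionless", K_Ret = "dimensionless", K_SCL = "dimensionless",
  K_Ep_Aq = "dimensionless", K_Ep_t = "dimensionless",
  P_Conj = "permeability", P_ScCh_Ret = "permeability",
  P_Ret_Vit = "permeability", P_t_Aq = "permeability",
  F = "fraction",
  H = "length", D_SCL = "diffusivity", C0_SCL = "concentration",
  n_nodes = "integer",
  M_Released = "mass", T = "time",
  t_end = "time", output_step = "time", rel_tol = "dimensionless",
  abs_tol = "dimensionless", seed = "integer"
)

# conversion factor to the internal unit of each kind
.ocupk_unit_table <- list(
  volume = c("mL" = 1, "ml" = 1, "L" = 1000, "l" = 1000,
             "uL" = 1e-3, "ul" = 1e-3, "µL" = 1e-3, "µl" = 1e-3,
             "μL" = 1e-3, "μl" = 1e-3),
  area = c("cm2" = 1, "cm^2" = 1, "cm²" = 1, "mm2" = 0.01,
           "mm^2" = 0.01, "mm²" = 0.01),
  flow = c("mL/s" = 1, "ml/s" = 1, "mL/min" = 1 / 60, "ml/min" = 1 / 60,
           "mL/h" = 1 / 3600, "ml/h" = 1 / 3600,
           "uL/s" = 1e-3, "ul/s" = 1e-3, "µl/s" = 1e-3,
           "μl/s" = 1e-3, "µL/s" = 1e-3, "μL/s" = 1e-3,
           "uL/min" = 1e-3 / 60, "ul/min" = 1e-3 / 60,
           "µl/min" = 1e-3 / 60, "μl/min" = 1e-3 / 60,
           "µL/min" = 1e-3 / 60, "μL/min" = 1e-3 / 60,
           "uL/h" = 1e-3 / 3600, "ul/h" = 1e-3 / 3600),
  permeability = c("cm/s" = 1, "cm/min" = 1 / 60, "cm/h" = 1 / 3600,
                   "um/s" = 1e-4, "µm/s" = 1e-4, "μm/s" = 1e-4),
  diffusivity = c("cm2/s" = 1, "cm^2/s" = 1, "cm²/s" = 1,
                  "cm2/min" = 1 / 60, "cm^2/min" = 1 / 60,
                  "m2/s" = 1e4, "m^2/s" = 1e4),
  length = c("cm" = 1, "mm" = 0.1, "um" = 1e-4, "µm" = 1e-4,
             "μm" = 1e-4, "m" = 100),
  concentration = c("ng/mL" = 1, "ng/ml" = 1, "ng/g" = 1,
                    "ug/mL" = 1e3, "ug/ml" = 1e3, "ug/g" = 1e3,
                    "µg/mL" = 1e3, "μg/mL" = 1e3,
                    "µg/ml" = 1e3, "μg/ml" = 1e3,
                    "mg/mL" = 1e6, "mg/ml" = 1e6),
  mass = c("ng" = 1, "ug" = 1e3, "µg" = 1e3, "μg" = 1e3,
           "mg" = 1e6, "g" = 1e9),
  time = c("s" = 1, "sec" = 1, "min" = 60, "h" = 3600, "hr" = 3600,
           "day" = 86400, "days" = 86400, "d" = 86400),
  fraction = c("%" = 0.01, "percent" = 0.01),
  dimensionless = c(),
  integer = c()
)

# printed rendering unit for each kind (used by params_as_printed)
.ocupk_print_units <- c(
  volume = "mL", area = "cm2", flow = "uL/min", permeability = "cm/s",
  diffusivity = "cm2/s", length = "cm", concentration = "ng/mL",
  mass = "ng", time = "s", fraction = "%", dimensionless = "",
  integer = ""
)

# Parse a single tagged value ("4.2 uL/min", "15", 7e-5) for a known key.
# Numeric input is taken to be already in internal units (idempotence).
.parse_quantity <- function(key, value) {
  kind <- unname(.ocupk_key_kinds[key])
  if (is.na(kind)) {
    stop("unrecognized parameter key: ", key, call. = FALSE)
  }
  if (is.numeric(value)) {
    return(as.numeric(value))
  }
  txt <- trimws(as.character(value))
  m <- regmatches(txt, regexec(
    "^([+-]?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)\\s*(.*)$", txt))[[1]]
  if (length(m) == 0L) {
    stop("cannot parse value for key ", key, ": '", txt, "'", call. = FALSE)
  }
  num <- as.numeric(m[2])
  unit <- trimws(m[3])
  if (unit == "") {
    if (kind %in% c("dimensionless", "integer", "fraction")) {
      return(num)
    }
    stop("missing unit tag for key ", key, " (kind '", kind, "')",
         call. = FALSE)
  }
  factors <- .ocupk_unit_table[[kind]]
  if (!unit %in% names(factors)) {
    stop("unknown unit tag '", unit, "' for key ", key, " (kind '", kind,
         "')", call. = FALSE)
  }
  num * factors[[unit]]
}

#' Normalize a raw parameter map into internal units
#'
#' Accepts a flat named list (or vector) whose values are either numbers
#' (interpreted as already normalized, which makes the operation idempotent)
#' or strings of the form `"<number> <unit>"` using any recognized unit tag
#' for that key, e.g. `Q_Aq = "4.2 uL/min"`, `Clearance_ScCh = "1 mL/min"`,
#' `F = "2.08 %"`. Returns an [ocular_params] object in the internal
#' {cm, mL, s, ng} system; `F` is stored as a fraction in `[0, 1]`.
#'
#' @param raw named list or character vector of parameter values, plus an
#'   optional `mode` entry (`"diffusion"` or `"release"`, default taken from
#'   the keys present).
#' @return an object of class `ocular_params`.
#' @export
#' @examples
#' p <- normalize_units(list(
#'   V_t = "7e-3 mL", V_Vit = "1.7 mL", V_ScCh = "0.361 mL",
#'   V_Ret = "0.086 mL", V_Aq = "0.325 mL", A_Globe = "8.6 cm2",
#'   A_Palp = "14 cm2", A_Bulb = "3 cm2",
#'   Q_UvSc = "0.176 uL/min", Q_Vit_Aq = "0.19 uL/min", Q_Aq = "4.2 uL/min",
#'   Q_Drain = "0.5 uL/min", Clearance_ScCh = "1 mL/min",
#'   K_t = 1, K_Aq = 1, K_Vit = 1, K_ScCh = 15, K_Ret = 10,
#'   P_Conj = "2.5e-6 cm/s", P_ScCh_Ret = "10e-6 cm/s",
#'   P_Ret_Vit = "13e-6 cm/s", F = "2.08 %",
#'   M_Released = "2e5 ng", T = "2 day", mode = "release"))
#' p$physiology$Q_Aq  # 7e-5 mL/s
normalize_units <- function(raw) {
  raw <- as.list(raw)
  mode <- raw$mode
  raw$mode <- NULL
  vals <- list()
  for (key in names(raw)) {
    vals[[key]] <- .parse_quantity(key, raw[[key]])
  }
  if (is.null(mode)) {
    mode <- if (!is.null(vals$M_Released) && is.null(vals$D_SCL)) {
      "release"
    } else {
      "diffusion"
    }
  }
  mode <- match.arg(mode, c("diffusion", "release"))

  pick <- function(keys) {
    out <- vals[intersect(keys, names(vals))]
    out
  }
  anatomy_keys <- c("V_t", "V_Vit", "V_ScCh", "V_Ret", "V_Aq", "A_Globe",
                    "A_Palp", "A_Bulb", "A_Cornea", "A_SCL")
  physiology_keys <- c("Q_UvSc", "Q_Vit_Aq", "Q_Aq", "Q_Drain",
                       "Clearance_ScCh")
  drug_keys <- c("K_t", "K_Aq", "K_Vit", "K_ScCh", "K_Ret", "K_SCL",
                 "K_Ep_Aq", "K_Ep_t", "P_Conj", "P_ScCh_Ret", "P_Ret_Vit",
                 "P_t_Aq", "F")
  lens_keys <- c("H", "D_SCL", "C0_SCL", "n_nodes")
  release_keys <- c("M_Released", "T")
  solver_keys <- c("t_end", "output_step", "rel_tol", "abs_tol", "seed")

  required <- c(anatomy_keys[1:8], physiology_keys,
                c("K_t", "K_ScCh", "K_Ret", "K_Vit", "P_Conj",
                  "P_ScCh_Ret", "P_Ret_Vit"))
  required <- c(required, if (mode == "release") {
    c("F", release_keys)
  } else {
    c("K_SCL", "P_t_Aq", lens_keys[1:3])
  })
  missing_keys <- setdiff(required, names(vals))
  if (length(missing_keys) > 0L) {
    stop("missing required key(s) for mode '", mode, "': ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }

  solver <- utils::modifyList(
    list(t_end = 604800, output_step = 600, rel_tol = 1e-8,
         abs_tol = 1e-12, seed = 1L),
    pick(solver_keys))
  lens <- NULL
  if (mode == "diffusion") {
    lens <- utils::modifyList(list(n_nodes = 50L), pick(lens_keys))
    lens$n_nodes <- as.integer(lens$n_nodes)
  }
  release <- NULL
  if (mode == "release") {
    rl <- pick(release_keys)
    release <- release_fit(M_Released = rl$M_Released, T = rl$T)
  }
  drug <- pick(drug_keys)
  # epithelium partition coefficients are optional (C_Ep is diagnostic)
  if (is.null(drug$K_Ep_Aq)) drug$K_Ep_Aq <- NA_real_
  if (is.null(drug$K_Ep_t)) drug$K_Ep_t <- NA_real_
  ocular_params(
    anatomy = pick(anatomy_keys),
    physiology = pick(physiology_keys),
    drug = drug,
    lens = lens,
    release = release,
    mode = mode,
    solver = solver)
}

#' Render a parameter set back to printed units
#'
#' Inverse of [normalize_units()] for reporting: converts the internal
#' {cm, mL, s, ng} values back to the conventional printed units
#' (volumes in mL, flows in uL/min except clearances in mL/min, permeabilities
#' in cm/s, F in percent).
#'
#' @param params an `ocular_params` object.
#' @return data.frame with columns `key`, `value`, `unit`.
#' @export
params_as_printed <- function(params) {
  stopifnot(inherits(params, "ocular_params"))
  flat <- flatten_params(params)
  keys <- names(flat)
  rows <- lapply(keys, function(key) {
    kind <- .ocupk_key_kinds[[key]]
    unit <- .ocupk_print_units[[kind]]
    val <- flat[[key]]
    if (kind == "flow") {
      if (key == "Clearance_ScCh") {
        unit <- "mL/min"
        val <- val * 60
      } else {
        val <- val * 60 * 1e3  # mL/s -> uL/min
      }
    } else if (kind == "fraction") {
      val <- val * 100
    }
    data.frame(key = key, value = val, unit = unit,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# flatten an ocular_params into a single named numeric list (scalars only)
flatten_params <- function(params) {
  out <- c(params$anatomy, params$physiology, params$drug)
  if (!is.null(params$lens)) {
    out <- c(out, params$lens)
  }
  if (!is.null(params$release)) {
    out <- c(out, list(M_Released = params$release$M_Released,
                       T = params$release$T))
  }
  out[!vapply(out, is.null, logical(1))]
}
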