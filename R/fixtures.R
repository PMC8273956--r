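# Bundled benchmark networks.
#
# car20 emulates the 20-node / 22-edge car-diagnosis benchmark: the original
# tool's conditional probabilities are proprietary, so the parameterisation
# here is a declared synthetic surrogate -- every variable is binary
# {ok, bad}, roots have P(ok) = 0.8 and every non-root follows the noisy
# threshold P(ok | parents) = max(0.05, 0.95 - 0.60 * #bad-parents), which is
# deterministic, portable, and strong enough for recovery experiments.
#
# sprinkler4 is the canonical cloudy/sprinkler/rain/wet-grass toy network,
# small enough for closed-form oracle checks.
#
# lipid10 is the 10-node / 14-arc hyperlipidemia survey network. Its
# Hyperlipidemia CPT is transcribed from the published conditional
# probability table (percentages to three decimals); all other CPTs are
# documented synthetic surrogates chosen so the enumerated marginal
# P(Hyperlipidemia = yes) lies in [0.42, 0.50].

car20_edges <- function() {
  data.frame(
    from = c(
      "BatteryAge", "Alternator", "ChargingSystem", "BatteryState", "MainFuse",
      "BatteryVoltage", "Distributor", "Distributor", "VoltageAtPlug",
      "SparkPlugs", "SparkTiming", "BatteryVoltage", "StarterMotor", "Starter",
      "BatteryVoltage", "FuelPump", "FuelSystem", "AirFilter", "AirSystem",
      "SparkQuality", "CarCranks", "BatteryVoltage"
    ),
    to = c(
      "BatteryState", "ChargingSystem", "BatteryState", "BatteryVoltage",
      "VoltageAtPlug", "VoltageAtPlug", "VoltageAtPlug", "SparkTiming",
      "SparkQuality", "SparkQuality", "SparkQuality", "Starter", "Starter",
      "CarCranks", "CarCranks", "FuelSystem", "CarStarts", "AirSystem",
      "CarStarts", "CarStarts", "CarStarts", "Headlights"
    )
  )
}

# P(ok | parents) for the car20 surrogate rule
noisy_threshold_ok <- function(n_bad) pmax(0.05, 0.95 - 0.60 * n_bad)

build_car20 <- function() {
  nodes <- c(
    "BatteryAge", "Alternator", "ChargingSystem", "BatteryState",
    "BatteryVoltage", "MainFuse", "Distributor", "VoltageAtPlug",
    "SparkPlugs", "SparkTiming", "SparkQuality", "StarterMotor", "Starter",
    "CarCranks", "FuelPump", "FuelSystem", "AirFilter", "AirSystem",
    "CarStarts", "Headlights"
  )
  dag <- bn_dag(nodes, car20_edges())
  levels <- stats::setNames(rep(list(c("ok", "bad")), length(nodes)), nodes)
  cpts <- lapply(nodes, function(v) {
    pa <- parents(dag, v)
    if (length(pa) == 0) {
      bn_cpt(v, character(0), levels, c(0.8, 0.2))
    } else {
      q <- 2^length(pa)
      cfg <- expand.grid(rep(list(c("ok", "bad")), length(pa)))
      n_bad <- rowSums(cfg == "bad")
      p_ok <- noisy_threshold_ok(n_bad)
      bn_cpt(v, pa, levels, rbind(p_ok, 1 - p_ok))
    }
  })
  names(cpts) <- nodes
  discrete_bn(levels, dag, cpts)
}

build_sprinkler4 <- function() {
  nodes <- c("Cloudy", "Sprinkler", "Rain", "WetGrass")
  dag <- bn_dag(nodes, data.frame(
    from = c("Cloudy", "Cloudy", "Sprinkler", "Rain"),
    to = c("Sprinkler", "Rain", "WetGrass", "WetGrass")
  ))
  levels <- stats::setNames(rep(list(c("T", "F")), 4), nodes)
  cpts <- list(
    Cloudy = bn_cpt("Cloudy", character(0), levels, c(0.5, 0.5)),
    Sprinkler = bn_cpt(
      "Sprinkler", "Cloudy", levels,
      rbind(c(0.1, 0.5), c(0.9, 0.5)) # P(T | Cloudy = T, F)
    ),
    Rain = bn_cpt(
      "Rain", "Cloudy", levels,
      rbind(c(0.8, 0.2), c(0.2, 0.8))
    ),
    WetGrass = bn_cpt(
      "WetGrass", c("Sprinkler", "Rain"), levels,
      # parent configs (Sprinkler, Rain): TT, FT, TF, FF in array order
      rbind(c(0.99, 0.90, 0.90, 0.00), c(0.01, 0.10, 0.10, 1.00))
    )
  )
  discrete_bn(levels, dag, cpts)
}

# Hyperlipidemia = yes (%) by (PhysicalActivity, Gender, BMI), transcribed
# from the published conditional probability table; "no" = 100 - yes.
lipid_cpt_yes <- function() {
  yes <- c(
    # Insufficient: male <18.5, 18.5~, 24.0~, 28.0~; then female
    35.149, 42.485, 62.074, 75.273,
    30.603, 42.336, 41.720, 62.112,
    # Normal
    5.189, 38.905, 56.312, 70.706,
    17.836, 29.592, 47.125, 56.547,
    # Sufficient
    47.642, 33.537, 56.358, 74.941,
    37.805, 35.827, 44.388, 51.761
  )
  # reorder from (BMI fastest within gender within activity) to array order
  # with parents (PhysicalActivity, Gender, BMI): activity fastest
  arr <- array(yes / 100, dim = c(4, 2, 3)) # BMI, Gender, Activity
  aperm(arr, c(3, 2, 1)) # Activity, Gender, BMI
}

lipid10_edges <- function() {
  data.frame(
    from = c(
      "Gender", "Gender", "Gender", "PhysicalActivity", "BMI",
      "PhysicalActivity", "BMI", "Hyperlipidemia", "Hyperlipidemia",
      "Smoking", "SaltIntake", "OilIntake", "CentralObesity", "CentralObesity"
    ),
    to = c(
      "Smoking", "PhysicalActivity", "Hyperlipidemia", "BMI", "Hyperlipidemia",
      "Hyperlipidemia", "CentralObesity", "Hypertension", "Diabetes",
      "Hypertension", "Hypertension", "Hypertension", "Hypertension", "Diabetes"
    )
  )
}

build_lipid10 <- function() {
  levels <- list(
    Gender = c("male", "female"),
    Smoking = c("no", "yes"),
    PhysicalActivity = c("Insufficient", "Normal", "Sufficient"),
    SaltIntake = c("<6g", "≥6g"),
    OilIntake = c("<25g", "≥25g"),
    BMI = c("<18.5", "18.5~", "24.0~", "28.0~"),
    CentralObesity = c("no", "yes"),
    Hyperlipidemia = c("no", "yes"),
    Hypertension = c("no", "yes"),
    Diabetes = c("no", "yes")
  )
  dag <- bn_dag(names(levels), lipid10_edges())

  # risky level of each Hypertension/Diabetes parent for the noisy threshold
  risky <- c(
    Hyperlipidemia = "yes", Smoking = "yes", SaltIntake = "≥6g",
    OilIntake = "≥25g", CentralObesity = "yes"
  )
  disease_cpt <- function(child, pa) {
    cfg <- expand.grid(levels[pa], KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n_bad <- rowSums(mapply(function(col, p) col == risky[[p]], cfg, pa))
    p_no <- noisy_threshold_ok(n_bad)
    bn_cpt(child, pa, levels, rbind(p_no, 1 - p_no))
  }

  hyper_yes <- lipid_cpt_yes() # dim (Activity 3, Gender 2, BMI 4)
  hyper <- array(0, dim = c(2, 3, 2, 4))
  hyper[1, , , ] <- 1 - hyper_yes
  hyper[2, , , ] <- hyper_yes

  cpts <- list(
    Gender = bn_cpt("Gender", character(0), levels, c(0.49, 0.51)),
    Smoking = bn_cpt(
      "Smoking", "Gender", levels,
      rbind(c(0.45, 0.95), c(0.55, 0.05)) # P(yes): male .55, female .05
    ),
    PhysicalActivity = bn_cpt(
      "PhysicalActivity", "Gender", levels,
      cbind(c(0.25, 0.45, 0.30), c(0.35, 0.45, 0.20))
    ),
    SaltIntake = bn_cpt("SaltIntake", character(0), levels, c(0.40, 0.60)),
    OilIntake = bn_cpt("OilIntake", character(0), levels, c(0.45, 0.55)),
    BMI = bn_cpt(
      "BMI", "PhysicalActivity", levels,
      cbind(
        c(0.04, 0.38, 0.38, 0.20), # Insufficient
        c(0.05, 0.45, 0.35, 0.15), # Normal
        c(0.06, 0.52, 0.32, 0.10) # Sufficient
      )
    ),
    CentralObesity = bn_cpt(
      "CentralObesity", "BMI", levels,
      rbind(
        1 - c(0.02, 0.35, 0.80, 0.97),
        c(0.02, 0.35, 0.80, 0.97)
      )
    ),
    Hyperlipidemia = bn_cpt(
      "Hyperlipidemia", c("PhysicalActivity", "Gender", "BMI"), levels, hyper
    ),
    Hypertension = disease_cpt(
      "Hypertension",
      c("Hyperlipidemia", "Smoking", "SaltIntake", "OilIntake", "CentralObesity")
    ),
    Diabetes = disease_cpt("Diabetes", c("Hyperlipidemia", "CentralObesity"))
  )
  discrete_bn(levels, dag, cpts)
}

fixture_notes <- c(
  car20 = paste(
    "20-node / 22-edge car-diagnosis benchmark structure with a synthetic",
    "surrogate parameterisation (binary {ok, bad}; roots P(ok) = 0.8;",
    "non-roots P(ok | parents) = max(0.05, 0.95 - 0.60 * #bad-parents))."
  ),
  sprinkler4 = "Canonical 4-node cloudy/sprinkler/rain/wet-grass network.",
  lipid10 = paste(
    "10-node / 14-arc hyperlipidemia survey network; the Hyperlipidemia CPT",
    "is transcribed from the published table, every other CPT is a",
    "documented synthetic surrogate."
  )
)

fixture_cache <- new.env(parent = emptyenv())

#' Load a bundled benchmark network
#'
#' Returns one of the immutable benchmark fixtures: `"car20"` (20 nodes, 22
#' edges), `"sprinkler4"` (4 nodes, 4 edges), or `"lipid10"` (10 nodes, 14
#' edges, the hyperlipidemia survey surrogate whose outcome CPT is the
#' published table).
#'
#' @param name Fixture name.
#' @return A `benchmark_fixture`: list with `name`, `network`
#'   (a [discrete_bn()]), and `notes` (provenance string).
#' @examples
#' fx <- load_fixture("sprinkler4")
#' fx$network
#' @export
load_fixture <- function(name) {
  if (!name %in% c("car20", "sprinkler4", "lipid10")) {
    rlang::abort(paste0("unknown fixture: ", name), class = "bnhybrid_error_unknown_fixture")
  }
  hit <- fixture_cache[[name]]
  if (is.null(hit)) {
    net <- switch(name,
      car20 = build_car20(),
      sprinkler4 = build_sprinkler4(),
      lipid10 = build_lipid10()
    )
    hit <- structure(
      list(name = name, network = net, notes = fixture_notes[[name]]),
      class = "benchmark_fixture"
    )
    fixture_cache[[name]] <- hit
  }
  hit
}

#' @export
print.benchmark_fixture <- function(x, ...) {
  cat("<benchmark_fixture> ", x$name, "\n  ", x$notes, "\n", sep = "")
  print(x$network)
  invisible(x)
}
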