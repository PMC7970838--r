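# Fixture builders shared across test files. All fields are constructed
# in code; no external data.

utc <- function(x) as.POSIXct(x, tz = "UTC")
EARTH_R <- 6371000

# constant-velocity field centred on (0, 0)
makeUniformField <- function(u0 = 0.5, v0 = 0, days = 3,
                             lon = seq(-2, 2, 0.5), lat = seq(-2, 2, 0.5)) {
  dates <- seq(as.Date("2017-06-01"), by = "day", length.out = days)
  dims <- c(length(lon), length(lat), 2, days)
  FlowField(lon, lat, c(0, 50), dates,
            u = array(u0, dims), v = array(v0, dims),
            maxSpeed = max(1, sqrt(u0^2 + v0^2) + 0.1))
}

# solid-body rotation about (0, 0): u = -omega*y, v = omega*x in local
# tangent-plane metres; period = 2*pi/omega seconds
makeRotationField <- function(period = 628319, days = 10,
                              lon = seq(-1.5, 1.5, 0.25)) {
  omega <- 2 * pi / period
  lat <- lon
  x <- EARTH_R * lon * pi / 180
  y <- EARTH_R * lat * pi / 180
  u2 <- -omega * outer(rep(1, length(lon)), y)
  v2 <- omega * outer(x, rep(1, length(lat)))
  dates <- seq(as.Date("2017-06-01"), by = "day", length.out = days)
  dims <- c(length(lon), length(lat), 2, days)
  FlowField(lon, lat, c(0, 50), dates,
            u = array(rep(u2, 2 * days), dims),
            v = array(rep(v2, 2 * days), dims), maxSpeed = 3)
}

makeParticle <- function(lon = 0, lat = 0, depth = 20, length = 9,
                         hatch = utc("2017-06-01"), status = "active") {
  data.frame(id = 1L, lon = lon, lat = lat, depth = depth, length = length,
             hatch_time = hatch, age = 0, ground = "g", status = status,
             stringsAsFactors = FALSE)
}

# droplet well at an exact positive fraction (possibly non-integer
# counts, for exact-arithmetic checks)
makeWell <- function(stomach = "s1", rep = 1, p = 0.5, nTotal = 20000,
                     dilution = 1) {
  data.frame(well_id = sprintf("%s-r%d", stomach, rep),
             stomach_id = stomach, replicate = rep, n_total = nTotal,
             n_positive = p * nTotal, dilution = dilution,
             stringsAsFactors = FALSE)
}

makeSubsample <- function(stomach = "s1", rep = 1, wet = 0.2) {
  data.frame(stomach_id = stomach, replicate = rep, wet_weight = wet,
             stringsAsFactors = FALSE)
}

makeStomach <- function(stomach = "s1", station = "A", year = 2017,
                        empty = FALSE) {
  data.frame(stomach_id = stomach, station_id = station, year = year,
             fish_weight = 400, content_weight = if (empty) 0.01 else 4,
             empty = empty, stringsAsFactors = FALSE)
}

# reverse complement for building references in tests
rcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

FWD <- "CGCCCACCAATCACGAA"
REV <- "ACGTTTGTGCCAGTATCACGTT"
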