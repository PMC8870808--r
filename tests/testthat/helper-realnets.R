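# Locations of the optional real-world network files (classic public
# datasets: American college football, network-science coauthorship,
# university e-mail, western US power grid). They are not bundled; when a
# copy is placed under inst/extdata/realnets/ (or the directory named by
# option "lwcent.realnet_dir"), the reproduction checks run on them.

real_network_path <- function(name) {
  candidates <- c(
    paste0(name, ".gml"), paste0(name, ".txt"),
    paste0(name, ".edges"), paste0(name, ".csv")
  )
  dirs <- c(
    getOption("lwcent.realnet_dir", ""),
    system.file("extdata", "realnets", package = "lwcent"),
    file.path(testthat::test_path(), "realnets")
  )
  for (d in dirs[nzchar(dirs)]) {
    for (f in candidates) {
      p <- file.path(d, f)
      if (file.exists(p)) return(p)
    }
  }
  NA_character_
}

load_real_network <- function(name) {
  p <- real_network_path(name)
  if (is.na(p)) return(NULL)
  g <- read_graph_file(p)
  if (name == "netscience") g <- largest_component(g)
  g
}
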