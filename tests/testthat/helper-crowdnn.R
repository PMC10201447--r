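# Shared fixtures: load the bundled tables once per test run.
ref_params <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- load_parameter_set()
    val
  }
})

ref_decomp <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- load_decomposition()
    val
  }
})

# Random fully complementary duplex (test-local generator, independent of
# simulate_duplex_set) for property-style checks.
random_duplex <- function(n = sample(4:12, 1)) {
  duplex_spec(paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                    collapse = ""))
}

# Write a parameter table to a temp TSV, optionally tampering with a cell.
write_param_tsv <- function(edit = NULL) {
  tab <- utils::read.delim(system.file("extdata", "nn_peg200_40wt_100mM_Na.tsv",
                                       package = "crowdnn"))
  if (!is.null(edit)) tab[tab$parameter == edit$parameter, edit$column] <- edit$value
  path <- tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
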