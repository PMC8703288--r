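# Embedded atomic-mass and isotope-abundance table (IUPAC/NIST 2021 values,
# masses in Da). This single table is the package's mass convention: the
# monoisotopic mass of an element is the mass of its most abundant isotope
# (first row of each entry), and isotope patterns are convolved from the
# per-isotope abundances below.
.isotope_table <- list(
  H  = list(mass = c(1.0078250319, 2.0141017778),
            abundance = c(0.999885, 0.000115)),
  C  = list(mass = c(12.0000000000, 13.0033548351),
            abundance = c(0.9893, 0.0107)),
  N  = list(mass = c(14.0030740044, 15.0001088989),
            abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.9949146196, 16.9991317565, 17.9991596129),
            abundance = c(0.99757, 0.00038, 0.00205)),
  S  = list(mass = c(31.9720711744, 32.9714589098, 33.9678670040, 35.9670807100),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P  = list(mass = 30.9737619984, abundance = 1),
  Na = list(mass = 22.9897692820, abundance = 1)
)

# proton and electron rest masses (Da); the protonated adduct uses the proton
# mass so that cation m/z values are electron-mass corrected
.proton_mass <- 1.007276467
.electron_mass <- 0.000548580

.supported_elements <- function() names(.isotope_table)

.monoisotopic_element_mass <- function(symbol) {
  entry <- .isotope_table[[symbol]]
  entry$mass[which.max(entry$abundance)]
}
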