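# vennwalk

Compare two or more differential-expression experiments by combining their
set structure with network propagation. vennwalk partitions the gene lists
into the disjoint regions of their Venn diagram, takes any union of regions
as seed genes, and ranks the remaining genes by a random walk with restart
over the high-confidence protein–protein interaction (PPI) subnetwork
induced on the gene union. It is aimed at analysts who already have called
DEG lists (from limma, DESeq2, edgeR, ...) and a STRING-style scored edge
list, and who want to ask questions like *"which genes specific to
condition A behave most like the genes specific to condition B?"*

## The method

With `n` experiments `E_1..E_n`, the DEG union splits into `2^n − 1`
disjoint regions `C_i`, indexed by binary membership codes: gene `g ∈ C_i`
iff for every `j`, `g ∈ E_j` exactly when digit `b_j` of `i` is 1 (`b_1`,
the least-significant digit, is the first input file; with three
experiments `C_7 = E_1 ∩ E_2 ∩ E_3`). A seed expression such as `"C2"` or
`"C2+C4"` selects a union of regions; the seed vector `p⁰` puts uniform
mass on those genes. Over the induced PPI graph (edges kept when the
STRING combined score is strictly greater than 700) with column-normalized
adjacency `A'`, the walk iterates

```
p(t+1) = (1 − r) A' p(t) + r p⁰        r = 0.5
```

until the L1 difference of consecutive iterates drops below `1e-4`. The
fixed point — equivalently the solution of `(I − (1−r)A') p = r p⁰` —
scores each gene by proximity to the seeds; non-seed genes are ranked by
descending score, optionally restricted to a target region.

## Worked example

The package ships a fixture generator that emulates all three inputs with
planted structure, so the example below is fully self-contained:

```r
library(vennwalk)

fx <- generate_fixture(fixture_spec(), "example")   # DEG lists, edges, alias
res <- run_pipeline(fx$deg_files, fx$edge_file, seed_expression = "C2",
                    labels = fx$labels, alias_path = fx$alias_file,
                    restrict_expression = "C1", output_dir = "example_out")

res$regionmap
#> <Venn partition of 2 experiments: 3 regions, 242 genes>
res$log$iterations; res$log$converged
#> 13
#> TRUE
head(res$ranked, 5)
#>   rank    gene      score region is_seed degree
#> 1    1 GEN0101 0.01714354     C1   FALSE     14
#> 2    2 GEN0165 0.01314900     C1   FALSE     12
#> 3    3 GEN0174 0.01195884     C1   FALSE     10
#> 4    4 GEN0162 0.01141612     C1   FALSE     10
#> 5    5 GEN0079 0.01083541     C1   FALSE     11
```

The 242 DEGs split into region `C1` (specific to experiment 1), `C2`
(specific to experiment 2) and `C3` (shared). Seeding on `C2` and
restricting to `C1` ranks the experiment-1-specific genes by functional
proximity to the experiment-2-specific ones; the walk converged in 13
iterations. In this planted instance the generator wired half of the `C1`
genes preferentially to `C2`, and those genes rise to the top: their
median rank is 16.5 versus 48.5 for the unwired `C1` genes. `example_out/`
holds `regions.tsv`, `ranked.tsv`, `run.log` and the echoed configuration.

The same pipeline is available from the shell:

```sh
Rscript inst/cli/vennwalk.R fixtures --out example
Rscript inst/cli/vennwalk.R run \
  --deg example/deg_1_E1.tsv,example/deg_2_E2.tsv \
  --ppi example/edges.txt --alias example/alias.tsv \
  --seeds C2 --restrict C1 --out example_out
```

Subcommand `partition` stops after writing the region summary, for users
who want to inspect the regions before choosing seeds. Exit codes
distinguish usage (2), input (3) and analysis (4) failures.

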