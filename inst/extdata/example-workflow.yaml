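rules:
  all:
    input:
    - plots/U0001.pdf
    - plots/U0002.pdf
  get_data:
    input: data/cities_raw.csv
    output: results/cities.csv
    shell: cp {input} {output}
    cache: no
    env: coreutils
  select_by_country:
    input: results/cities.csv
    output: results/by-country/{country}.csv
    temp:
    - 1
    shell: grep '^{wildcards.country},' {input} > {output}
    cache: no
    env: coreutils
  plot_histogram:
    input: results/by-country/{country}.csv
    output: plots/{country}.hist.txt
    shell: awk -F, '$1 != "country" { n=int($3/250000)+1; b=""; while (n-- > 0) b=b"#";
      print $2" "b }' {input} > {output}
    cache: no
    env: awk
  convert_to_pdf:
    input: plots/{country}.hist.txt
    output: plots/{country}.pdf
    shell: cp {input} {output}
    cache: no
    env: coreutils

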