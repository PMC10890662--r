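id,precursor_mz,rt,mz,intensity
GA7,401.2435,NA,95.0855,200
GA7,401.2435,NA,109.1012,150
GA7,401.2435,NA,337.2274,300
GA7,401.2435,NA,355.238,400
GA7,401.2435,NA,383.2329,500
GA7,401.2435,NA,401.2435,1000
GA34,419.254,NA,72.0808,200
GA34,419.254,NA,91.0542,150
GA34,419.254,NA,105.0699,120
GA34,419.254,NA,119.0855,100
GA34,419.254,NA,294.1852,250
GA34,419.254,NA,310.1802,300
GA34,419.254,NA,356.1856,400
GA34,419.254,NA,374.1962,500
GA34,419.254,NA,419.254,1000
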