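id,precursor_mz,rt,mz,intensity
compound1,563.2963,10.32,72.0808,300
compound1,563.2963,10.32,91.0542,250
compound1,563.2963,10.32,105.0699,200
compound1,563.2963,10.32,119.0855,150
compound1,563.2963,10.32,282.1489,150
compound1,563.2963,10.32,310.1802,350
compound1,563.2963,10.32,338.1751,400
compound1,563.2963,10.32,356.1856,600
compound1,563.2963,10.32,401.2435,800
compound1,563.2963,10.32,563.2963,1000
compound2,563.2963,12.1,72.0808,300
compound2,563.2963,12.1,91.0542,250
compound2,563.2963,12.1,105.0699,200
compound2,563.2963,12.1,119.0855,150
compound2,563.2963,12.1,282.1489,120
compound2,563.2963,12.1,310.1802,300
compound2,563.2963,12.1,338.1751,450
compound2,563.2963,12.1,356.1856,500
compound2,563.2963,12.1,401.2435,850
compound2,563.2963,12.1,563.2963,900
compound10,581.3069,10.77,72.0808,300
compound10,581.3069,10.77,91.0542,250
compound10,581.3069,10.77,105.0699,200
compound10,581.3069,10.77,119.0855,150
compound10,581.3069,10.77,294.1852,250
compound10,581.3069,10.77,310.1802,300
compound10,581.3069,10.77,356.1856,400
compound10,581.3069,10.77,374.1962,500
compound10,581.3069,10.77,419.254,600
compound10,581.3069,10.77,581.3069,1000
compound11,583.3225,8.7,72.0808,300
compound11,583.3225,8.7,91.0542,250
compound11,583.3225,8.7,105.0699,200
compound11,583.3225,8.7,119.0855,150
compound11,583.3225,8.7,302.1751,150
compound11,583.3225,8.7,330.2064,350
compound11,583.3225,8.7,358.2013,400
compound11,583.3225,8.7,376.2119,600
compound11,583.3225,8.7,421.2697,800
compound11,583.3225,8.7,583.3225,1000
compound12,611.3174,9.55,72.0808,300
compound12,611.3174,9.55,91.0542,250
compound12,611.3174,9.55,105.0699,200
compound12,611.3174,9.55,119.0855,150
compound12,611.3174,9.55,294.1489,100
compound12,611.3174,9.55,322.1802,250
compound12,611.3174,9.55,368.1856,300
compound12,611.3174,9.55,386.1962,400
compound12,611.3174,9.55,404.2068,600
compound12,611.3174,9.55,449.2646,800
compound12,611.3174,9.55,611.3174,1000
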