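kind,name,value
factor,lecithin,100
factor,chitosan,23.5
factor,ipm,2.6
estimated,PS,168.4
estimated,ZP,33.1
estimated,EE,82.3
expected,PS,179.1
expected,ZP,30.5
expected,EE,79.2
error_pct,PS,6.4
error_pct,ZP,7.9
error_pct,EE,3.8
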