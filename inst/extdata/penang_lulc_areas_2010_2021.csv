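class,area_ha_2010,area_ha_2021
urbanized,6111.62,8905.43
forests,12025.44,12213.70
agricultural,10456.32,6954.51
bare,425.44,1521.21
rocks,1495.07,722.89
water,189.12,385.27
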