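"compartment","t_day","t_night","table_avg_temp","realized_avg_temp","winter_lamp_hours","co2_sp","co2_capacity_kg_ha_h","init_stems","fruits_per_truss","truss_type","topping_date","supply_ec","brix_modifier","yield_seed1","income_seed1","net_profit_seed1"
301,21.7,20.2,21.34,21.17,15.5,900,110,3.8,15,"single","2020-04-30",3.01,0.05,14.09,36.02,7.75
302,22.7,21.2,22.04,21.94,15.25,900,100,2.6,16,"single","2020-04-16",3.21,0.15,13.24,33.53,6.97
303,23.35,21.85,22.7,22.49,15.5,750,60,4,14,"single","2020-04-17",3.61,-0.05,13.99,35.57,5.86
304,21.85,20.35,21.37,21.24,15,850,70,3.4,16,"single","2020-04-23",3.35,0,13.3,33.79,7.13
305,21.6,20.1,21.4,21.18,16.5,650,75,3,17,"split","2020-04-24",3.58,0.45,13.94,36.23,9.37
306,23.95,22.55,23.25,23.03,15.5,800,75,3,14,"single","2020-04-21",3.32,0.15,13.72,35.02,7.09
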