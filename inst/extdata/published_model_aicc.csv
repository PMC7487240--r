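response,model,aicc
sd_extent,pa_extent + winter_stratum,115.9
sd_extent,pa_extent + breeding_stratum,116
sd_extent,pa_extent + winter_stratum + day_length,117
sd_extent,pa_extent + winter_stratum + breeding_stratum,117.9
sd_extent,pa_extent,120.4
sd_extent,migration + breeding_stratum,131
sd_extent,migration + winter_stratum,131.8
sd_extent,migration + breeding_stratum + winter_stratum,132.7
sd_extent,winter_stratum + breeding_mean_temp,133.1
sd_extent,winter_stratum,134.1
sd_extent,breeding_stratum,134.3
sd_extent,migration,134.5
sd_extent,day_length,134.8
sd_extent,breeding_min_temp,134.9
sd_extent,migration_b,135.2
pa_extent,migration + day_length + breeding_solar,173.8
pa_extent,day_length + breeding_solar,175.8
pa_extent,migration,176.7
pa_extent,migration + breeding_solar,177
pa_extent,day_length + migration,177.8
pa_extent,day_length + breeding_solar + solar,178
pa_extent,migration + winter_solar,178.3
pa_extent,day_length,178.7
pa_extent,migration + winter_solar_b,178.9
pa_extent,day_length + solar,178.9
pa_extent,migration + solar,179
pa_extent,day_length + breeding_precip,180
pa_extent,day_length + winter_solar,180.2
pa_extent,day_length + breeding_stratum + winter_stratum + breeding_solar,180.3
pa_extent,day_length + breeding_min_temp,180.5
pa_extent,day_length + breeding_stratum,180.5
pa_extent,day_length + winter_stratum,182.9
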